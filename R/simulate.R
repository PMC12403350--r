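#' Simulation configuration for a parent-parent-F1 trio experiment
#'
#' Defines the generative model used by [simulate_trio_experiment()]. Gene
#' counts are negative binomial with `variance = mu + dispersion * mu^2`;
#' SNP-site depths are Poisson; hybrid allele counts are binomial with
#' success probability `2^H / (1 + 2^H)` for the P2 allele.
#'
#' Defaults describe a trio design with three biological replicates per
#' genotype per stage (each replicate a pool of plants, hence the low
#' default dispersion), a 1 log2-unit effect magnitude, and roughly 100x
#' coverage per SNP site.
#'
#' @param n_genes_per_class Named integer vector over the inheritance modes
#'   `additive`, `high_parent_dom`, `low_parent_dom`, `overdominant`,
#'   `underdominant`.
#' @param n_regulatory_per_class Named integer vector over the regulatory
#'   classes `cis_only`, `trans_only`, `cis_plus_trans`, `cis_times_trans`,
#'   `compensatory`, `conserved`.
#' @param baseline_mean Expected count for an unperturbed gene.
#' @param dispersion Negative-binomial dispersion (`variance = mu +
#'   dispersion * mu^2`).
#' @param effect_log2fc Magnitude (log2 units) of parental, dominance and
#'   allelic shifts.
#' @param snps_per_gene Parent-distinguishing SNP sites per gene.
#' @param site_depth_mean Mean hybrid read depth per SNP site.
#' @param n_replicates Biological replicates per genotype per stage.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes_per_class = c(additive = 100,
                                             high_parent_dom = 100,
                                             low_parent_dom = 100,
                                             overdominant = 100,
                                             underdominant = 100),
                       n_regulatory_per_class = c(cis_only = 100,
                                                  trans_only = 100,
                                                  cis_plus_trans = 75,
                                                  cis_times_trans = 75,
                                                  compensatory = 75,
                                                  conserved = 75),
                       baseline_mean = 500,
                       dispersion = 0.002,
                       effect_log2fc = 1,
                       snps_per_gene = 4,
                       site_depth_mean = 100,
                       n_replicates = 3,
                       seed = 1L) {
  inh_names <- setdiff(.inheritance_modes, "unclassified")
  reg_names <- setdiff(.regulatory_classes, "ambiguous")
  if (!all(names(n_genes_per_class) %in% inh_names)) {
    abort("n_genes_per_class names must be inheritance modes")
  }
  if (!all(names(n_regulatory_per_class) %in% reg_names)) {
    abort("n_regulatory_per_class names must be regulatory classes")
  }
  if (any(n_genes_per_class < 0) || any(n_regulatory_per_class < 0)) {
    abort("class sizes must be >= 0")
  }
  if (sum(n_genes_per_class) == 0 && sum(n_regulatory_per_class) == 0) {
    abort("at least one class must have genes")
  }
  if (n_replicates < 2) abort("n_replicates must be >= 2")
  if (dispersion <= 0) abort("dispersion must be > 0")
  if (effect_log2fc < 0) abort("effect_log2fc must be >= 0")
  if (baseline_mean <= 0 || site_depth_mean <= 0 || snps_per_gene < 1) {
    abort("baseline_mean, site_depth_mean, snps_per_gene must be positive")
  }
  structure(list(n_genes_per_class = n_genes_per_class,
                 n_regulatory_per_class = n_regulatory_per_class,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 effect_log2fc = effect_log2fc, snps_per_gene = snps_per_gene,
                 site_depth_mean = site_depth_mean,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# regulatory class -> (H_true, T_true) in units of the effect size; P = H + T
.reg_effects <- function(class, e) {
  switch(class,
    conserved       = c(H = 0,     T = 0),
    cis_only        = c(H = e,     T = 0),
    trans_only      = c(H = 0,     T = e),
    cis_plus_trans  = c(H = e,     T = e),
    cis_times_trans = c(H = e,     T = -e / 2),
    compensatory    = c(H = e,     T = -e),
    abort(paste("unknown regulatory class", class)))
}

#' Simulate a trio experiment with known ground truth
#'
#' Draws a gene-by-sample count matrix (three genotypes, two stages,
#' `n_replicates` replicates), per-role allele-count tables at simulated SNP
#' sites, a gene interval map, and the per-gene truth. Each gene carries
#' both an inheritance mode (driving the F1 mean in the count matrix) and a
#' regulatory class (driving parental and hybrid allele counts through
#' `P_true`, `H_true`, `T_true = P_true - H_true`).
#'
#' Genotype means: additive genes have F1 mean at the midparent; dominance
#' genes at the high/low parent; over/underdominant genes at
#' `2^(+/-effect)` times the extreme parent. The count-scale parental
#' divergence follows `P_true` where nonzero; dominance-mode genes whose
#' regulatory class gives `P_true = 0` receive a parental count shift of
#' `effect_log2fc` so their mode is realisable.
#'
#' @param config A [sim_config()].
#' @return List of class `trio_sim` with elements `counts`
#'   ([trio_counts]), `alleles` (per stage, tibbles `P1`, `P2`, `F1` in
#'   ASEReadCounter layout), `gene_map`, `gene_lengths`, `truth` (tibble),
#'   and `config`.
#' @export
simulate_trio_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  inh <- rep(names(config$n_genes_per_class), config$n_genes_per_class)
  reg <- rep(names(config$n_regulatory_per_class), config$n_regulatory_per_class)
  n <- max(length(inh), length(reg), 1L)
  inh <- c(inh, rep("additive", n - length(inh)))
  reg <- c(reg, rep("conserved", n - length(reg)))
  inh <- sample(inh); reg <- sample(reg)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  gene_ids <- sprintf("g%05d", seq_len(n))

  e <- config$effect_log2fc
  ht <- t(vapply(reg, .reg_effects, numeric(2), e = e))
  H_true <- unname(sgn * ht[, "H"])
  T_true <- unname(sgn * ht[, "T"])
  P_true <- H_true + T_true

  # count-scale parental divergence: follow P_true; make dominance modes
  # realisable when P_true is zero
  d <- P_true
  needs_div <- d == 0 & inh %in% c("high_parent_dom", "low_parent_dom")
  d[needs_div] <- sgn[needs_div] * e

  m1 <- config$baseline_mean * 2^(-d / 2)
  m2 <- config$baseline_mean * 2^(+d / 2)
  hi <- pmax(m1, m2); lo <- pmin(m1, m2)
  mF1 <- dplyr::case_when(
    inh == "additive" ~ (m1 + m2) / 2,
    inh == "high_parent_dom" ~ hi,
    inh == "low_parent_dom" ~ lo,
    inh == "overdominant" ~ 2^e * hi,
    inh == "underdominant" ~ 2^(-e) * lo)
  dominant_parent_true <- dplyr::case_when(
    inh == "high_parent_dom" & m1 >= m2 ~ "P1",
    inh == "high_parent_dom" ~ "P2",
    inh == "low_parent_dom" & m1 <= m2 ~ "P1",
    inh == "low_parent_dom" ~ "P2",
    TRUE ~ "none")

  truth <- tibble::tibble(
    gene_id = gene_ids, inheritance_mode = inh, regulatory_class = reg,
    P_true = P_true, H_true = H_true, T_true = T_true,
    parental_count_log2fc = d, dominant_parent_true = dominant_parent_true)

  r <- config$n_replicates
  size <- 1 / config$dispersion
  samples <- tidyr::expand_grid(genotype = .genotypes, stage = .stages,
                                replicate = seq_len(r))
  samples$sample_id <- sprintf("%s_%s_r%d", samples$genotype, samples$stage,
                               samples$replicate)
  mu_by_geno <- cbind(P1 = m1, P2 = m2, F1 = mF1)
  counts <- vapply(seq_len(nrow(samples)), function(j) {
    rnbinom(n, mu = mu_by_geno[, samples$genotype[j]], size = size)
  }, numeric(n))
  rownames(counts) <- gene_ids
  colnames(counts) <- samples$sample_id
  cm <- trio_counts(counts, samples[, c("sample_id", "genotype", "stage",
                                        "replicate")])

  # gene intervals: 1 kb per gene on one contig, sites spaced inside
  k <- config$snps_per_gene
  gene_map <- tibble::tibble(
    contig = "chr1",
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = seq_len(n) * 1000L,
    gene_id = gene_ids)
  site_gene <- rep(seq_len(n), each = k)
  position <- gene_map$start[site_gene] + 100L * (seq_len(k) - 1L)
  parent_of_ref <- ifelse(seq_along(site_gene) %% 2L == 1L, "P1", "P2")

  p2_prob <- 2^H_true / (1 + 2^H_true)
  d1_mean <- config$site_depth_mean * 2^(-P_true / 2)
  d2_mean <- config$site_depth_mean * 2^(+P_true / 2)

  alleles <- lapply(setNames(.stages, .stages), function(stg) {
    d1 <- rpois(length(site_gene), d1_mean[site_gene])
    d2 <- rpois(length(site_gene), d2_mean[site_gene])
    nh <- rpois(length(site_gene), config$site_depth_mean)
    h2 <- rbinom(length(site_gene), nh, p2_prob[site_gene])
    h1 <- nh - h2
    ref_is_p1 <- parent_of_ref == "P1"
    mk <- function(ref_count, alt_count) tibble::tibble(
      contig = "chr1", position = position,
      refAllele = ifelse(ref_is_p1, "A", "G"),
      altAllele = ifelse(ref_is_p1, "G", "A"),
      refCount = ref_count, altCount = alt_count,
      totalCount = ref_count + alt_count)
    list(P1 = mk(ifelse(ref_is_p1, d1, 0L), ifelse(ref_is_p1, 0L, d1)),
         P2 = mk(ifelse(ref_is_p1, 0L, d2), ifelse(ref_is_p1, d2, 0L)),
         F1 = mk(ifelse(ref_is_p1, h1, h2), ifelse(ref_is_p1, h2, h1)))
  })

  structure(list(counts = cm, alleles = alleles, gene_map = gene_map,
                 gene_lengths = setNames(rep(2000, n), gene_ids),
                 truth = truth, config = config),
            class = "trio_sim")
}

#' Simulate a null experiment (no effects anywhere)
#'
#' All genes are additive and conserved with zero effect sizes, keeping the
#' total gene count of `config`. Used to estimate false-positive rates of
#' every downstream caller.
#'
#' @param config A [sim_config()].
#' @return A `trio_sim`, as from [simulate_trio_experiment()].
#' @export
simulate_null <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- max(sum(config$n_genes_per_class), sum(config$n_regulatory_per_class))
  null_cfg <- sim_config(
    n_genes_per_class = c(additive = n),
    n_regulatory_per_class = c(conserved = n),
    baseline_mean = config$baseline_mean, dispersion = config$dispersion,
    effect_log2fc = 0, snps_per_gene = config$snps_per_gene,
    site_depth_mean = config$site_depth_mean,
    n_replicates = config$n_replicates, seed = config$seed)
  simulate_trio_experiment(null_cfg)
}

#' Write the files of a simulated experiment
#'
#' Emits `counts.tsv`, `samples.tsv`, `genes.bed`, `gene_lengths.tsv`,
#' `alleles_<stage>_<role>.tsv` and `truth.tsv` under `dir`, in the formats
#' the readers in this package consume.
#'
#' @param sim A `trio_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "trio_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- sim$config$seed
  cm <- tibble::as_tibble(sim$counts$counts, rownames = "gene_id")
  write_trio_table(cm, file.path(dir, "counts.tsv"), seed = seed)
  write_trio_table(sim$counts$samples[, c("sample_id", "genotype", "stage",
                                          "replicate")],
                   file.path(dir, "samples.tsv"), seed = seed)
  readr::write_tsv(sim$gene_map, file.path(dir, "genes.bed"),
                   col_names = FALSE)
  write_trio_table(tibble::tibble(gene_id = names(sim$gene_lengths),
                                  length = unname(sim$gene_lengths)),
                   file.path(dir, "gene_lengths.tsv"), seed = seed)
  for (stg in names(sim$alleles)) {
    for (role in names(sim$alleles[[stg]])) {
      write_trio_table(sim$alleles[[stg]][[role]],
                       file.path(dir, sprintf("alleles_%s_%s.tsv", stg, role)),
                       seed = seed)
    }
  }
  write_trio_table(sim$truth, file.path(dir, "truth.tsv"), seed = seed)
  invisible(dir)
}

#' Joined allele sites of a simulated stage
#'
#' Convenience wrapper running [read_allele_counts()] on the in-memory
#' allele tables of one simulated stage.
#'
#' @param sim A `trio_sim`.
#' @param stage `"AN"` or `"GF"`.
#' @return An `allele_sites` tibble.
#' @export
sim_allele_sites <- function(sim, stage = "AN") {
  stopifnot(inherits(sim, "trio_sim"), stage %in% names(sim$alleles))
  a <- sim$alleles[[stage]]
  read_allele_counts(a$P1, a$P2, a$F1, sim$gene_map)
}
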