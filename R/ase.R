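#' Quality-filter SNP sites for allele-specific expression
#'
#' Filters run in a fixed order, and each removed site is tallied under its
#' first failing reason:
#'
#' 1. minimum depth: hybrid depth and both parental depths `>= min_depth`;
#' 2. depth tails: hybrid site depth within the
#'    `[depth_tail, 1 - depth_tail]` percentile band of the hybrid
#'    site-depth distribution, computed over the sites retained so far;
#' 3. reference skew (mapping-bias guard, switchable): the hybrid ref:alt
#'    ratio must satisfy `1/ref_skew <= ref:alt <= ref_skew`.
#'
#' Indels never reach this stage; they are rejected at parse time by
#' [read_allele_counts()].
#'
#' @param sites `allele_sites` tibble.
#' @param min_depth Minimum read depth (default 10).
#' @param depth_tail Tail mass trimmed from each end of the hybrid depth
#'   distribution (default 0.05).
#' @param ref_skew Maximum tolerated hybrid reference-allele skew
#'   (default 2); `NULL` or `Inf` disables the filter.
#' @return List with `sites` (retained tibble) and `log` (tibble `reason`,
#'   `n`).
#' @export
filter_sites <- function(sites, min_depth = 10, depth_tail = 0.05,
                         ref_skew = 2) {
  sites <- tibble::as_tibble(sites)
  log <- list()
  if (!nrow(sites)) {
    warn("empty site list")
    return(list(sites = sites, log = tibble::tibble(reason = character(),
                                                    n = integer())))
  }
  hybrid_depth <- sites$hybrid_count_p1_allele + sites$hybrid_count_p2_allele

  keep <- hybrid_depth >= min_depth &
    sites$count_p1_sample >= min_depth & sites$count_p2_sample >= min_depth
  log$min_depth <- sum(!keep)
  sites <- sites[keep, ]; hybrid_depth <- hybrid_depth[keep]

  if (nrow(sites)) {
    qs <- quantile(hybrid_depth, c(depth_tail, 1 - depth_tail), names = FALSE)
    keep <- hybrid_depth >= qs[1] & hybrid_depth <= qs[2]
    log$depth_tail <- sum(!keep)
    sites <- sites[keep, ]
  } else log$depth_tail <- 0L

  if (!is.null(ref_skew) && is.finite(ref_skew) && nrow(sites)) {
    ref <- ifelse(sites$parent_of_ref == "P1",
                  sites$hybrid_count_p1_allele, sites$hybrid_count_p2_allele)
    alt <- ifelse(sites$parent_of_ref == "P1",
                  sites$hybrid_count_p2_allele, sites$hybrid_count_p1_allele)
    ratio <- ref / alt   # alt = 0 gives Inf and is rejected
    keep <- is.finite(ratio) & ratio <= ref_skew & ratio >= 1 / ref_skew
    log$ref_skew <- sum(!keep)
    sites <- sites[keep, ]
  } else log$ref_skew <- 0L

  list(sites = sites,
       log = tibble::tibble(reason = names(log),
                            n = unlist(log, use.names = FALSE)))
}

#' Exact binomial test of allelic balance at one or more sites
#'
#' Two-sided exact binomial p-value against a 0.5 allele ratio, the
#' minimum-likelihood definition (sum of outcome probabilities not
#' exceeding that of the observed outcome).
#'
#' @param p1_count,p2_count Reads supporting each parental allele.
#' @return Numeric vector of p-values; `NA` where the total is 0 (such
#'   sites are skipped upstream).
#' @export
site_binomial_test <- function(p1_count, p2_count) {
  binom_pvalue(p2_count, p1_count + p2_count, p = 0.5)
}

#' Aggregate retained sites to gene-level ASE measurements
#'
#' Hybrid allele counts are summed across a gene's retained sites, the
#' exact binomial test is re-run on the sums, and sites whose individual
#' bias direction opposes the gene-level direction are counted as
#' discordant. Genes appear only if they have at least one retained site
#' (the SNP-qualified universe).
#'
#' @param sites Retained `allele_sites` tibble (from [filter_sites()]).
#' @return Tibble with `gene_id`, `n_sites_used`, `count_p1_allele`,
#'   `count_p2_allele`, `ratio` (P2-allele share), `p`.
#' @export
aggregate_gene_ase <- function(sites) {
  sites <- tibble::as_tibble(sites)
  gene <- sites |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_sites_used = dplyr::n(),
      count_p1_allele = sum(.data$hybrid_count_p1_allele),
      count_p2_allele = sum(.data$hybrid_count_p2_allele),
      discordant_sites = {
        gene_dir <- sign(sum(.data$hybrid_count_p2_allele) -
                         sum(.data$hybrid_count_p1_allele))
        site_dir <- sign(.data$hybrid_count_p2_allele -
                         .data$hybrid_count_p1_allele)
        if (gene_dir == 0) 0L else sum(site_dir == -gene_dir)
      },
      .groups = "drop") |>
    dplyr::filter(.data$count_p1_allele + .data$count_p2_allele > 0)
  gene$ratio <- gene$count_p2_allele /
    (gene$count_p1_allele + gene$count_p2_allele)
  gene$p <- site_binomial_test(gene$count_p1_allele, gene$count_p2_allele)
  gene
}

#' Classify gene-level allelic expression
#'
#' Adds BH q-values over the SNP-qualified gene family and assigns each
#' gene one class:
#'
#' * `monoallelic`: `q < q_cutoff` and ratio `>= ratio_mono` or
#'   `<= 1 - ratio_mono` (the mirrored tail keeps the rule
#'   parent-agnostic);
#' * `preferential`: `q < q_cutoff` and ratio `>= ratio_pref` or
#'   `<= 1 - ratio_pref`;
#' * `biallelic`: `q >= q_cutoff` and ratio strictly between
#'   `1 - ratio_pref` and `ratio_pref`;
#' * `undetermined`: the remaining (significance, ratio) cells, reported
#'   rather than silently assigned.
#'
#' `bias` is `P2` for ratio above 0.5, `P1` below, `none` at exactly 0.5 or
#' for biallelic genes.
#'
#' @param gene_ase Tibble from [aggregate_gene_ase()].
#' @param q_cutoff,ratio_mono,ratio_pref Thresholds (defaults 0.05, 0.95,
#'   0.67).
#' @return Input tibble with `q`, `ase_class`, `bias` columns.
#' @export
classify_ase <- function(gene_ase, q_cutoff = 0.05, ratio_mono = 0.95,
                         ratio_pref = 0.67) {
  gene_ase <- tibble::as_tibble(gene_ase)
  gene_ase$q <- bh_adjust(gene_ase$p)
  r <- gene_ase$ratio; q <- gene_ase$q
  sig <- q < q_cutoff
  cls <- dplyr::case_when(
    sig & (r >= ratio_mono | r <= 1 - ratio_mono) ~ "monoallelic",
    sig & (r >= ratio_pref | r <= 1 - ratio_pref) ~ "preferential",
    !sig & r > 1 - ratio_pref & r < ratio_pref ~ "biallelic",
    TRUE ~ "undetermined")
  gene_ase$ase_class <- cls
  gene_ase$bias <- dplyr::case_when(
    cls == "biallelic" ~ "none",
    r > 0.5 ~ "P2",
    r < 0.5 ~ "P1",
    TRUE ~ "none")
  gene_ase
}

#' Compare allelic bias between two stages
#'
#' Per gene present at both stages, the joint state over
#' `{P1 bias, P2 bias, no bias}` (a gene is biased when its deviation is
#' significant, `q < q_cutoff`, and directional). Genes observed at only
#' one stage are excluded from the cross-tab and counted in the coverage
#' summary.
#'
#' @param ase_an,ase_gf Classified tibbles from [classify_ase()].
#' @param q_cutoff Significance cutoff.
#' @return List with `crosstab` (state_an, state_gf, n) and `summary`
#'   (stable-bias, switched, newly biased, lost-bias and coverage counts).
#' @export
compare_ase_stages <- function(ase_an, ase_gf, q_cutoff = 0.05) {
  state <- function(d) {
    dplyr::mutate(tibble::as_tibble(d),
                  state = ifelse(.data$q < q_cutoff & .data$bias != "none",
                                 paste0(.data$bias, "_bias"), "no_bias"))[,
                  c("gene_id", "state")]
  }
  an <- state(ase_an); gf <- state(ase_gf)
  common <- dplyr::inner_join(an, gf, by = "gene_id",
                              suffix = c("_an", "_gf"))
  states <- c("P1_bias", "P2_bias", "no_bias")
  crosstab <- common |>
    dplyr::mutate(state_an = factor(.data$state_an, levels = states),
                  state_gf = factor(.data$state_gf, levels = states)) |>
    dplyr::count(.data$state_an, .data$state_gf, .drop = FALSE)
  biased_an <- common$state_an != "no_bias"
  biased_gf <- common$state_gf != "no_bias"
  summary <- tibble::tibble(
    n_common = nrow(common),
    n_excluded = nrow(an) + nrow(gf) - 2 * nrow(common),
    stable_bias = sum(biased_an & common$state_an == common$state_gf),
    switched_p1_to_p2 = sum(common$state_an == "P1_bias" &
                            common$state_gf == "P2_bias"),
    switched_p2_to_p1 = sum(common$state_an == "P2_bias" &
                            common$state_gf == "P1_bias"),
    newly_biased = sum(!biased_an & biased_gf),
    lost_bias = sum(biased_an & !biased_gf))
  list(crosstab = crosstab, summary = summary)
}

#' Summarise ASE calling per stage
#'
#' Headline accounting of a classified ASE table: the SNP-qualified gene
#' count, the number and fraction of ASE genes (significant, directional
#' bias), and the per-parent bias split among them.
#'
#' @param gene_ase Classified tibble from [classify_ase()] (optionally with
#'   a `stage` column).
#' @param q_cutoff Significance cutoff.
#' @return Tibble with `n_snp_qualified`, `n_ase`, `ase_gene_pct`,
#'   `n_bias_p1`, `n_bias_p2`, `bias_p1_share_pct`, `bias_p2_share_pct`,
#'   per stage when a `stage` column is present.
#' @export
tabulate_ase <- function(gene_ase, q_cutoff = 0.05) {
  gene_ase <- tibble::as_tibble(gene_ase)
  grp <- if ("stage" %in% names(gene_ase)) "stage" else character()
  gene_ase |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_snp_qualified = dplyr::n(),
      n_ase = sum(.data$q < q_cutoff & .data$bias != "none"),
      ase_gene_pct = 100 * n_ase / n_snp_qualified,
      n_bias_p1 = sum(.data$q < q_cutoff & .data$bias == "P1"),
      n_bias_p2 = sum(.data$q < q_cutoff & .data$bias == "P2"),
      bias_p1_share_pct = ifelse(n_ase > 0, 100 * n_bias_p1 / n_ase,
                                 NA_real_),
      bias_p2_share_pct = ifelse(n_ase > 0, 100 * n_bias_p2 / n_ase,
                                 NA_real_),
      .groups = "drop")
}
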