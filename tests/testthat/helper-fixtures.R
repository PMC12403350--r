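# Small in-code fixtures shared across test files.

# minimal 18-sample design (3 genotypes x 2 stages x 3 replicates)
fixture_samples <- function() {
  s <- expand.grid(genotype = c("P1", "P2", "F1"), stage = c("AN", "GF"),
                   replicate = 1:3, stringsAsFactors = FALSE)
  s$sample_id <- sprintf("%s_%s_r%d", s$genotype, s$stage, s$replicate)
  s[, c("sample_id", "genotype", "stage", "replicate")]
}

fixture_counts <- function(n_genes = 3, fill = NULL) {
  s <- fixture_samples()
  set.seed(99)
  m <- matrix(if (is.null(fill)) rpois(n_genes * nrow(s), 100) else fill,
              nrow = n_genes, ncol = nrow(s),
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              s$sample_id))
  trio_counts(m, s)
}

# hand-built allele site rows on the retained-site schema
site_row <- function(gene_id, p1s, p2s, h1, h2, parent_of_ref = "P1",
                     contig = "chr1", position = 1L) {
  tibble::tibble(contig = contig, position = position, gene_id = gene_id,
                 ref_allele = "A", alt_allele = "G",
                 parent_of_ref = parent_of_ref,
                 count_p1_sample = p1s, count_p2_sample = p2s,
                 hybrid_count_p1_allele = h1, hybrid_count_p2_allele = h2)
}

# one gene's four contrasts in the layout trio_contrasts() emits
contrast_row <- function(gene_id, q_mpv, q_p1, q_p2, q_pp = 0.5,
                         lfc_p1 = 0, lfc_p2 = 0, lfc_mpv = 0, lfc_pp = 0,
                         mean_p1 = 200, mean_p2 = 100, stage = "AN") {
  tibble::tibble(
    gene_id = gene_id, stage = stage,
    contrast = c("F1_vs_MPV", "F1_vs_P1", "F1_vs_P2", "P1_vs_P2"),
    log2fc = c(lfc_mpv, lfc_p1, lfc_p2, lfc_pp),
    p = c(q_mpv, q_p1, q_p2, q_pp),
    q = c(q_mpv, q_p1, q_p2, q_pp),
    mean_p1 = mean_p1, mean_p2 = mean_p2)
}

small_recovery_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_genes_per_class = c(additive = 60, high_parent_dom = 60,
                              low_parent_dom = 60, overdominant = 60,
                              underdominant = 60),
        n_regulatory_per_class = c(cis_only = 75, trans_only = 75,
                                   compensatory = 75, conserved = 75),
        seed = 20260926L)
      cache <<- simulate_trio_experiment(cfg)
    }
    cache
  }
})

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}
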