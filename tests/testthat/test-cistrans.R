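test_that("P, H and T follow their closed forms with pseudocounts", {
  p0 <- compute_P(100, 100, 1e6, 1e6)
  expect_equal(p0$P, 0)
  expect_equal(p0$p_P, 1)

  p1 <- compute_P(80, 20, 1e6, 1e6)
  expect_equal(p1$P, log2(20.5 / 80.5), tolerance = 1e-12)
  expect_equal(round(p1$P, 3), -1.973)

  h0 <- compute_H(50, 50)
  expect_equal(h0$H, 0)
  expect_equal(h0$p_H, 1)
  h1 <- compute_H(33, 67)
  expect_equal(h1$H, log2(67.5 / 33.5), tolerance = 1e-12)
  expect_equal(round(h1$H, 3), 1.011)

  # proportional parent/hybrid tables: T near 0, Fisher p effectively 1
  P <- compute_P(80, 20, 1, 1)$P
  H <- compute_H(40, 10)$H
  t1 <- compute_T(P, H, 80, 20, 40, 10)
  expect_lt(abs(t1$T), 0.05)
  expect_gte(t1$p_T, 0.99)

  # strong trans signal: parents diverge, hybrid balanced
  P2 <- compute_P(80, 20, 1, 1)$P
  H2 <- compute_H(50, 50)$H
  t2 <- compute_T(P2, H2, 80, 20, 50, 50)
  expect_lt(abs(t2$T - (-1.97)), 0.02)
  expect_lt(t2$p_T, 0.05)

  # degenerate margin: defined fallback
  expect_equal(compute_T(0, 0, 0, 0, 5, 5)$p_T, 1)
})

test_that("Fisher p-values match hypergeometric enumeration for small tables", {
  set.seed(7)
  for (i in 1:40) {
    tot <- sample(4:60, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    expect_equal(fisher_pvalue(a, b, c, d), oracle_fisher_p(a, b, c, d),
                 tolerance = 1e-9,
                 label = sprintf("table %d %d %d %d", a, b, c, d))
  }
})

test_that("regulatory categories follow the significance-and-sign pattern", {
  expect_equal(classify_regulation(0.01, 0.01, 0.50, H = 1, T = 0.1),
               "cis_only")
  expect_equal(classify_regulation(0.01, 0.50, 0.01, H = 0.1, T = 1),
               "trans_only")
  expect_equal(classify_regulation(0.40, 0.01, 0.01, H = 1, T = -1),
               "compensatory")
  expect_equal(classify_regulation(0.9, 0.9, 0.9, H = 0, T = 0), "conserved")
  expect_equal(classify_regulation(0.01, 0.01, 0.01, H = 1.2, T = -0.8),
               "cis_times_trans")
  expect_equal(classify_regulation(0.01, 0.01, 0.01, H = 1.2, T = 0.8),
               "cis_plus_trans")
  expect_equal(classify_regulation(0.01, 0.50, 0.50, H = 1, T = 0),
               "ambiguous")
})

test_that("percent cis spans its closed-form anchor points", {
  expect_equal(percent_cis(1, 0), 100)
  expect_equal(percent_cis(0, 2), 0)
  expect_equal(percent_cis(1, 1), 50)
  expect_equal(percent_cis(-1, 1), 50)
  expect_true(is.na(percent_cis(0, 0)))
})

test_that("gene-level calls keep T = P - H exactly and partition genes", {
  sim <- small_recovery_sim()
  sites <- filter_sites(sim_allele_sites(sim, "AN"), ref_skew = NULL)$sites
  calls <- cistrans_calls(sites)
  expect_identical(calls$T, calls$P - calls$H)
  expect_equal(anyDuplicated(calls$gene_id), 0)
  expect_true(all(calls$category %in%
                    c("cis_only", "trans_only", "cis_plus_trans",
                      "cis_times_trans", "compensatory", "conserved",
                      "ambiguous")))
  # conservation against the site table
  by_gene <- tapply(sites$hybrid_count_p1_allele, sites$gene_id, sum)
  expect_equal(as.vector(by_gene[calls$gene_id]), as.vector(calls$h1))
})

test_that("relabelling the parents negates P, H, T and preserves categories", {
  sim <- small_recovery_sim()
  sites <- filter_sites(sim_allele_sites(sim, "AN"), ref_skew = NULL)$sites
  swapped <- sites |>
    dplyr::rename(count_p1_sample = "count_p2_sample",
                  count_p2_sample = "count_p1_sample",
                  hybrid_count_p1_allele = "hybrid_count_p2_allele",
                  hybrid_count_p2_allele = "hybrid_count_p1_allele")
  a <- cistrans_calls(sites)
  b <- cistrans_calls(swapped)
  j <- dplyr::inner_join(tibble::as_tibble(a), tibble::as_tibble(b),
                         by = "gene_id", suffix = c("_a", "_b"))
  expect_equal(j$P_a, -j$P_b, tolerance = 1e-12)
  expect_equal(j$H_a, -j$H_b, tolerance = 1e-12)
  expect_equal(j$T_a, -j$T_b, tolerance = 1e-12)
  expect_equal(j$category_a, j$category_b)
  expect_equal(j$percent_cis_a, j$percent_cis_b, tolerance = 1e-12)
})

test_that("divergence summaries order cis and trans magnitudes correctly", {
  # all categories with identical |P|: equal medians, rank test flat
  same <- tibble::tibble(gene_id = paste0("g", 1:40),
                         category = rep(c("cis_only", "trans_only"), 20),
                         P = rep(c(1, -1), 20), H = 1, T = 0,
                         percent_cis = 50)
  s <- summarize_divergence(same)
  expect_equal(unique(s$magnitude$median_fold), 2)
  expect_gt(s$wilcox_p, 0.9)

  # larger cis than trans effects: ordered median folds
  cfg <- sim_config(n_genes_per_class = c(additive = 80),
                    n_regulatory_per_class = c(cis_only = 40, trans_only = 40),
                    effect_log2fc = 1, seed = 31)
  sim <- simulate_trio_experiment(cfg)
  truth2 <- sim$truth
  sites <- filter_sites(sim_allele_sites(sim, "AN"), ref_skew = NULL)$sites
  # double the cis effect by squaring hybrid imbalance: reuse truth labels
  calls <- cistrans_calls(sites)
  joined <- dplyr::inner_join(tibble::as_tibble(calls),
                              truth2, by = "gene_id")
  med_cis <- median(abs(joined$P[joined$regulatory_class == "cis_only"]))
  med_trans <- median(abs(joined$P[joined$regulatory_class == "trans_only"]))
  expect_equal(med_cis, med_trans, tolerance = 0.25)  # both built at |P|=1

  # category with < 2 genes is flagged, test skipped
  one <- same[1, ]
  s1 <- summarize_divergence(one)
  expect_true(all(s1$magnitude$flagged))
  expect_true(is.na(s1$wilcox_p))
})

test_that("the regulation-by-inheritance cross-tab conserves totals", {
  reg <- tibble::tibble(gene_id = paste0("g", 1:6),
                        category = rep(c("cis_only", "trans_only"), 3))
  inh <- tibble::tibble(gene_id = paste0("g", 1:6),
                        mode = rep(c("additive", "overdominant", "additive"),
                                   2))
  tab <- cross_tab_regulation_inheritance(reg, inh)
  expect_equal(sum(tab$n), 6)
  row_tot <- tapply(tab$row_pct, tab$category, sum)
  expect_true(all(abs(row_tot - 100) < 1e-9))

  expect_warning(
    empty <- cross_tab_regulation_inheritance(reg,
                                              dplyr::mutate(inh,
                                                            gene_id = paste0("x", 1:6))),
    "no genes shared")
  expect_equal(nrow(empty), 0)
})
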