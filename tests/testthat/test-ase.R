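test_that("site QC applies depth, tail and skew filters in order", {
  base <- site_row("gA", p1s = 50, p2s = 50, h1 = 20, h2 = 20)
  shallow <- site_row("gA", 50, 50, 5, 4)           # hybrid depth 9
  skewed <- site_row("gA", 50, 50, 21, 10)          # ref:alt 2.1
  boundary <- site_row("gA", 50, 50, 20, 10)        # ref:alt exactly 2
  sites <- dplyr::bind_rows(base, shallow, skewed, boundary)
  out <- filter_sites(sites, min_depth = 10, depth_tail = 0, ref_skew = 2)
  expect_equal(out$log$n[out$log$reason == "min_depth"], 1)
  expect_equal(out$log$n[out$log$reason == "ref_skew"], 1)
  expect_equal(nrow(out$sites), 2)                  # base + boundary retained

  # parental depth below threshold also rejects
  thin_parent <- site_row("gA", 9, 50, 20, 20)
  expect_equal(filter_sites(dplyr::bind_rows(base, thin_parent),
                            depth_tail = 0)$log$n[1], 1)

  expect_warning(filter_sites(base[0, ]), "empty")
})

test_that("depth-tail trimming removes exactly the extreme 5% on a 100-site fixture", {
  depths <- 101:200   # distinct depths
  sites <- purrr::map_dfr(seq_along(depths), function(i) {
    site_row("gA", 500, 500, depths[i] - 50, 50, position = i)
  })
  out <- filter_sites(sites, min_depth = 10, depth_tail = 0.05,
                      ref_skew = NULL)
  kept_depths <- out$sites$hybrid_count_p1_allele + out$sites$hybrid_count_p2_allele
  expect_equal(sort(kept_depths), 106:195)
  expect_equal(out$log$n[out$log$reason == "depth_tail"], 10)
})

test_that("exact binomial p-values match enumeration and known points", {
  expect_equal(site_binomial_test(5, 5), 1.0)
  expect_equal(site_binomial_test(10, 0), 2 * 0.5^10)
  expect_lt(site_binomial_test(67, 33), 0.05)
  # enumeration oracle over all totals <= 30
  for (n in c(1, 7, 18, 30)) {
    for (x in 0:n) {
      expect_equal(binom_pvalue(x, n), oracle_binom_p(x, n),
                   tolerance = 1e-10)
    }
  }
  # biased-null case used by the parental-divergence test
  expect_equal(binom_pvalue(5, 20, p = 0.3), oracle_binom_p(5, 20, 0.3),
               tolerance = 1e-10)
  expect_true(is.na(binom_pvalue(0, 0)))
})

test_that("gene aggregation conserves counts and flags discordant sites", {
  two <- dplyr::bind_rows(site_row("gA", 50, 50, 30, 10, position = 1),
                          site_row("gA", 50, 50, 30, 10, position = 2))
  agg <- aggregate_gene_ase(two)
  expect_equal(agg$count_p1_allele, 60)
  expect_equal(agg$count_p2_allele, 20)
  expect_equal(agg$ratio, 0.25)
  expect_equal(agg$discordant_sites, 0L)

  opp <- dplyr::bind_rows(site_row("gB", 50, 50, 40, 10, position = 1),
                          site_row("gB", 50, 50, 10, 40, position = 2))
  agg2 <- aggregate_gene_ase(opp)
  expect_equal(agg2$count_p1_allele, 50)
  expect_equal(agg2$ratio, 0.5)
  # tied gene direction: discordance defined as 0
  expect_equal(agg2$discordant_sites, 0L)

  mixed <- dplyr::bind_rows(site_row("gC", 50, 50, 40, 10, position = 1),
                            site_row("gC", 50, 50, 30, 10, position = 2),
                            site_row("gC", 50, 50, 10, 40, position = 3))
  expect_equal(aggregate_gene_ase(mixed)$discordant_sites, 1L)
})

test_that("ASE classes cover every (q, ratio) cell exactly once", {
  tbl <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    n_sites_used = 1L, count_p1_allele = 0L, count_p2_allele = 0L,
    discordant_sites = 0L,
    ratio = c(0.96, 0.70, 0.50, 0.80),
    p = c(0.0001, 0.002, 0.80, 0.20))
  cls <- classify_ase(tbl)
  # q = BH over 4 p-values keeps the significance pattern here
  expect_equal(cls$ase_class,
               c("monoallelic", "preferential", "biallelic", "undetermined"))
  expect_equal(cls$bias, c("P2", "P2", "none", "P2"))

  # totality: a grid of ratio x q always yields exactly one class
  grid <- tidyr::expand_grid(ratio = seq(0, 1, by = 0.01),
                             p = c(1e-6, 0.2, 0.9))
  grid$gene_id <- paste0("x", seq_len(nrow(grid)))
  grid$count_p1_allele <- 0L; grid$count_p2_allele <- 0L
  grid$n_sites_used <- 1L; grid$discordant_sites <- 0L
  cls2 <- classify_ase(grid)
  expect_true(all(cls2$ase_class %in% c("monoallelic", "preferential",
                                        "biallelic", "undetermined")))
  # mirrored monoallelic tail
  low <- classify_ase(tibble::tibble(gene_id = "m", ratio = 0.03,
                                     p = 1e-6))
  expect_equal(low$ase_class, "monoallelic")
  expect_equal(low$bias, "P1")
})

test_that("stage comparison counts stable, switched and new biases", {
  mk <- function(ids, ratio, q) tibble::tibble(gene_id = ids, ratio = ratio,
                                               q = q,
                                               bias = ifelse(ratio > 0.5, "P2",
                                                      ifelse(ratio < 0.5, "P1",
                                                             "none")))
  an <- mk(paste0("g", 1:5), c(0.8, 0.2, 0.5, 0.9, 0.1),
           c(0.01, 0.01, 0.9, 0.01, 0.01))
  # identical stages: diagonal, nothing switched
  cmp <- compare_ase_stages(an, an)
  expect_equal(cmp$summary$switched_p1_to_p2 + cmp$summary$switched_p2_to_p1, 0)
  expect_equal(cmp$summary$stable_bias, 4)

  gf <- an
  gf$ratio[1] <- 0.2; gf$bias[1] <- "P1"      # P2 -> P1 switch
  gf$q[2] <- 0.5                               # lost bias
  gf <- dplyr::bind_rows(gf, mk("g9", 0.9, 0.01))  # AN-missing gene
  cmp2 <- compare_ase_stages(an, gf)
  expect_equal(cmp2$summary$n_common, 5)
  expect_equal(cmp2$summary$n_excluded, 1)
  expect_equal(cmp2$summary$switched_p2_to_p1, 1)
  expect_equal(cmp2$summary$lost_bias, 1)
  expect_equal(cmp2$summary$stable_bias, 2)   # g4 and g5 keep their bias
})

test_that("ASE accounting recovers bias shares and gene fractions", {
  mk_stage <- function(stage, n_p1, n_p2, n_quiet) {
    tibble::tibble(
      gene_id = sprintf("%s%05d", stage, seq_len(n_p1 + n_p2 + n_quiet)),
      stage = stage,
      ratio = rep(c(0.2, 0.8, 0.5), c(n_p1, n_p2, n_quiet)),
      q = rep(c(0.01, 0.01, 0.5), c(n_p1, n_p2, n_quiet)),
      bias = rep(c("P1", "P2", "none"), c(n_p1, n_p2, n_quiet)))
  }
  an <- mk_stage("AN", 963, 881, 5982 - 1844)
  tab <- tabulate_ase(an)
  expect_equal(tab$n_ase, 1844)
  expect_equal(round(tab$ase_gene_pct, 1), 30.8)
  expect_equal(round(tab$bias_p1_share_pct, 1), 52.2)
})
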