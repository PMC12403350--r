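test_that("median-of-ratios size factors behave on closed-form toys", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 30), s2 = 2 * c(10, 20, 30))
  rownames(m2) <- paste0("g", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)          # ratio preserved
  expect_equal(exp(mean(log(sf))), 1)             # geometric mean 1

  # invariant to gene reordering
  perm <- c(3, 1, 2)
  expect_equal(size_factors(m2[perm, ]), sf)

  # all-zero-in-some-sample matrix falls back to library sizes
  m3 <- cbind(s1 = c(0, 10), s2 = c(10, 0))
  rownames(m3) <- paste0("g", 1:2)
  expect_warning(sf3 <- size_factors(m3), "library-size")
  expect_equal(unname(sf3), c(1, 1))
})

test_that("fpkm follows the closed form and its invariances", {
  s <- fixture_samples()[1, , drop = FALSE]
  s <- rbind(s, within(s, {sample_id <- "x2"; replicate <- 2L}))
  m <- matrix(c(1000, 1000, 9999000, 9999000), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gFill"), s$sample_id))
  cm <- trio_counts(m, s)   # library size 1e7 per sample
  f <- fpkm(cm, c(gA = 2000, gFill = 1000))
  expect_equal(unname(f["gA", ]), c(50, 50))      # 1000*1e9/(2000*1e7)
  expect_equal(unname(fpkm(cm, c(gA = 2000, gFill = 1000))["gA", 1] * 0), 0)

  # scale invariance: c times counts and library leaves FPKM unchanged
  m2 <- m * 3
  cm2 <- trio_counts(m2, s)
  expect_equal(fpkm(cm2, c(gA = 2000, gFill = 1000)), f)

  expect_error(fpkm(cm, c(gA = 2000)), "gFill")
})

test_that("expression bins use left-inclusive thresholds and partition genes", {
  s <- fixture_samples()
  vals <- c(55, 50, 49.9, 20, 19.9, 1, 0.99, 0)
  f <- matrix(rep(vals, times = nrow(s)), ncol = nrow(s),
              dimnames = list(paste0("g", seq_along(vals)), s$sample_id))
  bins <- fpkm_bins(f, tibble::as_tibble(s))
  an <- bins[bins$stage == "AN", ]
  expect_equal(an$bin[match(paste0("g", 1:8), an$gene_id)],
               c("high", "high", "moderate", "moderate", "low", "low",
                 "not_expressed", "not_expressed"))
  # partition: every gene binned exactly once per stage
  expect_equal(nrow(bins), length(vals) * 2)
  expect_error(fpkm_bins(f - 100, tibble::as_tibble(s)), "non-negative")
})

test_that("midparent pseudo-samples average paired parental replicates", {
  cm <- fixture_counts(1, fill = 100)
  cm$counts[1, cm$samples$genotype == "P2"] <- 200L
  cm$counts[1, cm$samples$genotype == "F1"] <- 150L
  mpv <- make_midparent(cm, "AN", sf = rep(1, 18))
  expect_equal(unname(mpv[1, ]), c(150, 150, 150))

  # identical parents reproduce either parent
  cm2 <- fixture_counts(2, fill = 120)
  mpv2 <- make_midparent(cm2, "GF", sf = rep(1, 18))
  expect_true(all(mpv2 == 120))
})

test_that("the built-in contrast engine matches t.test and handles edge cases", {
  set.seed(42)
  a <- matrix(rpois(300, 100), ncol = 3)
  b <- matrix(rpois(300, 150), ncol = 3)
  rownames(a) <- rownames(b) <- paste0("g", 1:100)
  res <- test_contrast(a, b)
  # cross-check every p against stats::t.test on the same transform
  pref <- vapply(1:100, function(i) {
    stats::t.test(log2(a[i, ] + 0.5), log2(b[i, ] + 0.5))$p.value
  }, numeric(1))
  expect_equal(res$p, pref, tolerance = 1e-12)

  # identical groups: lfc 0, p 1
  res0 <- test_contrast(a, a)
  expect_true(all(res0$log2fc == 0))
  expect_false(any(duplicated(res0$gene_id)))
  expect_true(all(res0$p == 1))

  # all-zero gene: defined result
  z <- matrix(0, nrow = 1, ncol = 3, dimnames = list("gz", NULL))
  resz <- test_contrast(z, z)
  expect_equal(resz$log2fc, 0)
  expect_equal(resz$p, 1)
})

test_that("BH adjustment equals the step-up oracle and keeps its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  for (m in c(1, 7, 100)) {
    p <- runif(m)^2
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
})

test_that("DEG thresholds are inclusive on fold change, strict on q", {
  res <- tibble::tibble(gene_id = c("a", "b", "c"),
                        log2fc = c(1.0, 0.99, 3),
                        p = c(0.01, 0.0005, 0.02),
                        q = c(0.04, 0.001, 0.05))
  expect_equal(call_degs(res)$is_deg, c(TRUE, FALSE, FALSE))
})

test_that("a simulated 4-fold change at depth 500 is detected in >= 90% of genes", {
  cfg <- sim_config(n_genes_per_class = c(additive = 150),
                    n_regulatory_per_class = c(cis_only = 150),
                    effect_log2fc = 2, baseline_mean = 500, seed = 12)
  sim <- simulate_trio_experiment(cfg)
  ctr <- trio_contrasts(sim$counts, "AN")
  pp <- ctr[ctr$contrast == "P1_vs_P2", ]
  hit <- dplyr::inner_join(pp, sim$truth, by = "gene_id") |>
    dplyr::filter(abs(.data$P_true) == 2)
  expect_gte(mean(hit$q < 0.05), 0.9)
})

test_that("external per-contrast tables can replace the built-in engine", {
  cm <- fixture_counts(3)
  ext <- tidyr::expand_grid(gene_id = rownames(cm$counts),
                            contrast = c("F1_vs_MPV", "F1_vs_P1",
                                         "F1_vs_P2", "P1_vs_P2"))
  ext$log2fc <- c(2, rep(0, nrow(ext) - 1))
  ext$p <- c(0.001, rep(0.8, nrow(ext) - 1))
  res <- trio_contrasts(cm, "AN", external = ext)
  expect_equal(nrow(res), nrow(ext))
  sub <- res[res$contrast == "F1_vs_MPV", ]
  expect_equal(sub$q, bh_adjust(sub$p))
  expect_error(trio_contrasts(cm, "AN", external = ext[ext$contrast !=
                                                         "P1_vs_P2", ]),
               "P1_vs_P2")
})
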