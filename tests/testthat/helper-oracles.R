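# Independent oracles, kept deliberately naive: direct enumeration and the
# literal step-up definition, never the package's own code paths.

# exact two-sided binomial p by full outcome enumeration
oracle_binom_p <- function(x, n, p = 0.5) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# two-sided Fisher p for [[a, b], [c, d]] by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# BH step-up by its definition: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# deterministic midparent-style worked means
expect_close <- function(x, y, tol = 1e-8) expect_equal(x, y, tolerance = tol)

# 2-dp rounding as printed trait tables do
round_half_away2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100
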