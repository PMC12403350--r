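#' Exact two-sided binomial test p-values, vectorised
#'
#' Wraps [stats::binom.test()] over paired count vectors. The two-sided
#' p-value is the minimum-likelihood definition: the sum of probabilities of
#' all outcomes no more probable than the observed one under the null.
#'
#' @param x Successes (numeric vector).
#' @param n Totals (numeric vector, recycled against `x`).
#' @param p Null success probability (scalar or vector).
#' @return Numeric vector of p-values; `NA` where `n == 0`.
#' @export
#' @examples
#' binom_pvalue(5, 10)            # 1
#' binom_pvalue(10, 10)           # 2 * 0.5^10 * ... exact tail
binom_pvalue <- function(x, n, p = 0.5) {
  m <- max(length(x), length(n), length(p))
  x <- rep_len(x, m); n <- rep_len(n, m); p <- rep_len(p, m)
  vapply(seq_len(m), function(i) {
    if (is.na(n[i]) || n[i] == 0) return(NA_real_)
    stats::binom.test(x[i], n[i], p = p[i], alternative = "two.sided")$p.value
  }, numeric(1))
}

#' Fisher's exact test on 2x2 count tables, vectorised
#'
#' Two-sided Fisher test on tables `[[a, b], [c, d]]` (rows are the two
#' samples, columns the two alleles). A table with a zero margin is
#' uninformative and returns p = 1.
#'
#' @param a,b,c,d Cell counts (vectors, recycled).
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_pvalue <- function(a, b, c, d) {
  m <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, m); b <- rep_len(b, m)
  c <- rep_len(c, m); d <- rep_len(d, m)
  vapply(seq_len(m), function(i) {
    tab <- matrix(c(a[i], c[i], b[i], d[i]), nrow = 2L)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"` so every module
#' shares one adjustment route. `NA` p-values propagate to `NA` q-values and
#' are not counted in the family size.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of q-values, same length as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

# Row-wise Welch two-sample test on matrices a (genes x nA) and b (genes x nB).
# Zero pooled standard error: p = 1 when means agree, p = 0 otherwise.
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  stopifnot(na >= 2, nb >= 2)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero & ma == mb] <- 1
  p[zero & ma != mb] <- 0
  tstat[zero] <- NA_real_
  list(statistic = tstat, df = df, p = p)
}

# round half away from zero, the convention of printed trait tables
round_half_away <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
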