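#' Parental expression divergence P for one gene
#'
#' `P = log2((c2 + 0.5) / (c1 + 0.5)) - log2(s2 / s1)` where `c1`, `c2` are
#' summed per-parent read counts at the gene's retained SNP sites and `s1`,
#' `s2` the parental library sizes. The p-value is an exact binomial test
#' of `c2` against `c1 + c2` with null proportion `s2 / (s1 + s2)`, so the
#' null and the effect size share the same normalisation.
#'
#' @param c1,c2 Summed parental counts (vectors allowed).
#' @param s1,s2 Parental library sizes.
#' @return Tibble with `P` and `p_P`.
#' @export
compute_P <- function(c1, c2, s1, s2) {
  tibble::tibble(
    P = log2((c2 + 0.5) / (c1 + 0.5)) - log2(s2 / s1),
    p_P = binom_pvalue(c2, c1 + c2, p = s2 / (s1 + s2)))
}

#' Hybrid allelic divergence H (the cis component) for one gene
#'
#' `H = log2((h2 + 0.5) / (h1 + 0.5))` from summed hybrid allele counts;
#' p-value from the exact binomial test against 0.5.
#'
#' @param h1,h2 Summed hybrid reads on the P1 and P2 alleles.
#' @return Tibble with `H` and `p_H`.
#' @export
compute_H <- function(h1, h2) {
  tibble::tibble(H = log2((h2 + 0.5) / (h1 + 0.5)),
                 p_H = binom_pvalue(h2, h1 + h2, p = 0.5))
}

#' Trans component T = P - H
#'
#' The point estimate is the exact identity `T = P - H`; significance comes
#' from a two-sided Fisher exact test of the 2x2 table
#' `[[c1, c2], [h1, h2]]` (parental counts versus hybrid allele counts). A
#' degenerate table (zero margin) gives p = 1.
#'
#' @param P,H Component estimates.
#' @param c1,c2,h1,h2 The four counts.
#' @return Tibble with `T` and `p_T`.
#' @export
compute_T <- function(P, H, c1, c2, h1, h2) {
  tibble::tibble(T = P - H, p_T = fisher_pvalue(c1, c2, h1, h2))
}

#' Classify regulatory divergence from the (P, H, T) significance pattern
#'
#' With `sig = q < q_cutoff`:
#' P and H significant, T not -> `cis_only`; P and T significant, H not ->
#' `trans_only`; all three significant and H, T in the same direction ->
#' `cis_plus_trans` (synergistic), in opposite directions ->
#' `cis_times_trans` (antagonistic); H and T significant, P not ->
#' `compensatory`; none significant -> `conserved`; every remaining
#' pattern -> `ambiguous`.
#'
#' @param q_P,q_H,q_T BH-adjusted p-values.
#' @param H,T Signed component estimates (only their signs are used).
#' @param q_cutoff Significance cutoff.
#' @return Character vector of categories.
#' @export
classify_regulation <- function(q_P, q_H, q_T, H, T, q_cutoff = 0.05) {
  sP <- q_P < q_cutoff; sH <- q_H < q_cutoff; sT <- q_T < q_cutoff
  dplyr::case_when(
    sP & sH & !sT ~ "cis_only",
    sP & !sH & sT ~ "trans_only",
    sP & sH & sT & sign(H) * sign(T) > 0 ~ "cis_plus_trans",
    sP & sH & sT ~ "cis_times_trans",
    !sP & sH & sT ~ "compensatory",
    !sP & !sH & !sT ~ "conserved",
    TRUE ~ "ambiguous")
}

#' Percent contribution of cis regulation to total divergence
#'
#' `100 * |H| / (|H| + |T|)`; undefined (`NA`) when both components are
#' exactly zero, and such genes are excluded from binned summaries.
#'
#' @param H,T Component estimates.
#' @return Numeric vector in `[0, 100]` (or `NA`).
#' @export
percent_cis <- function(H, T) {
  tot <- abs(H) + abs(T)
  ifelse(tot > 0, 100 * abs(H) / tot, NA_real_)
}

#' Per-gene cis/trans regulatory calls for one stage
#'
#' Sums parental and hybrid allele counts over each gene's retained SNP
#' sites, computes P, H and T with their exact tests, BH-adjusts each
#' statistic across genes as its own family, classifies the divergence
#' category and the percent-cis contribution. Genes whose summed hybrid or
#' parental depth falls below `min_depth` are excluded and counted in the
#' attached `"log"` attribute.
#'
#' @param sites Retained `allele_sites` tibble (from [filter_sites()]).
#' @param library_sizes Optional numeric `c(s1, s2)` parental library
#'   sizes; defaults to the total retained-site parental counts.
#' @param q_cutoff Significance cutoff.
#' @param min_depth Minimum summed depth per gene (default 10).
#' @return Tibble with per-gene counts, `P`, `H`, `T`, their p- and
#'   q-values, `category` and `percent_cis`.
#' @export
cistrans_calls <- function(sites, library_sizes = NULL, q_cutoff = 0.05,
                           min_depth = 10) {
  sites <- tibble::as_tibble(sites)
  gene <- sites |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(c1 = sum(.data$count_p1_sample),
                     c2 = sum(.data$count_p2_sample),
                     h1 = sum(.data$hybrid_count_p1_allele),
                     h2 = sum(.data$hybrid_count_p2_allele),
                     .groups = "drop")
  low <- gene$c1 + gene$c2 < min_depth | gene$h1 + gene$h2 < min_depth
  log_tbl <- tibble::tibble(reason = "below_min_depth", n = sum(low))
  gene <- gene[!low, ]
  if (!nrow(gene)) {
    warn("no gene passes the depth requirement")
    out <- tibble::tibble()
    attr(out, "log") <- log_tbl
    return(out)
  }
  if (is.null(library_sizes)) {
    library_sizes <- c(sum(gene$c1), sum(gene$c2))
  }
  s1 <- library_sizes[1]; s2 <- library_sizes[2]

  pp <- compute_P(gene$c1, gene$c2, s1, s2)
  hh <- compute_H(gene$h1, gene$h2)
  tt <- compute_T(pp$P, hh$H, gene$c1, gene$c2, gene$h1, gene$h2)
  out <- dplyr::bind_cols(gene, pp, hh, tt)
  out$q_P <- bh_adjust(out$p_P)
  out$q_H <- bh_adjust(out$p_H)
  out$q_T <- bh_adjust(out$p_T)
  out$category <- classify_regulation(out$q_P, out$q_H, out$q_T,
                                      out$H, out$T, q_cutoff)
  out$percent_cis <- percent_cis(out$H, out$T)
  attr(out, "log") <- log_tbl
  out
}

#' Magnitude and percent-cis summaries of regulatory divergence
#'
#' Per category: gene count, median `|P|` and the corresponding fold change
#' `2^median|P|`. A two-sided rank-sum (Wilcoxon) test compares the `|P|`
#' distributions of cis-only versus trans-only genes (skipped, with a flag,
#' when either category has fewer than two genes). Percent-cis means are
#' binned by `|P|` in fixed-width bins on the log2 scale.
#'
#' @param calls Tibble from [cistrans_calls()].
#' @param bin_width Width of the `|P|` bins (log2 units, default 0.5).
#' @return List with `magnitude` (per-category medians), `wilcox_p`
#'   (cis-only vs trans-only, `NA` when skipped), and `percent_cis_bins`.
#' @export
summarize_divergence <- function(calls, bin_width = 0.5) {
  calls <- tibble::as_tibble(calls)
  magnitude <- calls |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(),
                     median_abs_P = median(abs(.data$P)),
                     median_fold = 2^median(abs(.data$P)),
                     flagged = dplyr::n() < 2,
                     .groups = "drop")
  cis <- abs(calls$P[calls$category == "cis_only"])
  trans <- abs(calls$P[calls$category == "trans_only"])
  wilcox_p <- if (length(cis) >= 2 && length(trans) >= 2) {
    p <- wilcox.test(cis, trans, alternative = "two.sided",
                     exact = FALSE)$p.value
    if (is.nan(p)) 1 else p   # fully tied samples carry no evidence
  } else NA_real_
  binned <- calls |>
    dplyr::filter(!is.na(.data$percent_cis)) |>
    dplyr::mutate(bin = bin_width * ceiling(abs(.data$P) / bin_width)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_percent_cis = mean(.data$percent_cis),
                     .groups = "drop")
  list(magnitude = magnitude, wilcox_p = wilcox_p, percent_cis_bins = binned)
}

#' Cross-tabulate regulatory categories against inheritance modes
#'
#' Counts and row percentages of inheritance modes within each regulatory
#' category over the shared gene universe.
#'
#' @param reg_calls Tibble from [cistrans_calls()].
#' @param inh_calls Tibble from [classify_inheritance()].
#' @return Tibble with `category`, `mode`, `n`, `row_pct`.
#' @export
cross_tab_regulation_inheritance <- function(reg_calls, inh_calls) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(reg_calls), "gene_id", "category"),
    dplyr::select(tibble::as_tibble(inh_calls), "gene_id", "mode"),
    by = "gene_id")
  if (!nrow(joined)) {
    warn("no genes shared between regulatory and inheritance calls")
    return(tibble::tibble(category = character(), mode = character(),
                          n = integer(), row_pct = numeric()))
  }
  joined |>
    dplyr::count(.data$category, .data$mode) |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(row_pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
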