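#' Mid-parent heterosis percentage
#'
#' `MPH = 100 * (mean(F1) - MP) / MP` with `MP` the mean of the two
#' parental means. Errors when `MP <= 0`.
#'
#' @param p1,p2,f1 Replicate measurements (or single means) per genotype.
#' @return MPH percentage (unrounded).
#' @export
#' @examples
#' mid_parent_heterosis(10.8, 9.2, 15.2)  # 52
mid_parent_heterosis <- function(p1, p2, f1) {
  mp <- (mean(p1) + mean(p2)) / 2
  if (mp <= 0) abort("midparent value must be positive")
  100 * (mean(f1) - mp) / mp
}

#' Better-parent heterosis percentage
#'
#' `BPH = 100 * (mean(F1) - BP) / BP` with `BP` the higher-value parental
#' mean, regardless of agronomic desirability (so a shorter hybrid than the
#' taller parent yields a negative BPH). Errors when `BP <= 0`.
#'
#' @inheritParams mid_parent_heterosis
#' @return BPH percentage (unrounded).
#' @export
#' @examples
#' better_parent_heterosis(78.3, 112.0, 100.6)  # about -10.18
better_parent_heterosis <- function(p1, p2, f1) {
  bp <- max(mean(p1), mean(p2))
  if (bp <= 0) abort("better-parent value must be positive")
  100 * (mean(f1) - bp) / bp
}

#' Significance of mid- and better-parent heterosis
#'
#' `p_MPH` from a two-sided Welch test of the F1 replicates against
#' per-replicate midparent pseudo-values (the mean of the parental
#' replicates paired by sorted replicate order); `p_BPH` from a Welch test
#' of F1 against the better parent's replicates. Zero variance in both
#' groups with equal means gives p = 1.
#'
#' @param p1,p2,f1 Replicate measurements per genotype (at least 2 each).
#' @return Named numeric vector `c(p_MPH = ..., p_BPH = ...)`.
#' @export
heterosis_significance <- function(p1, p2, f1) {
  if (length(p1) < 2 || length(p2) < 2 || length(f1) < 2) {
    abort("at least 2 replicates per genotype are required")
  }
  r <- min(length(p1), length(p2))
  mp <- (p1[seq_len(r)] + p2[seq_len(r)]) / 2
  bp <- if (mean(p1) >= mean(p2)) p1 else p2
  welch1 <- function(a, b) {
    wa <- welch_rows(matrix(a, nrow = 1), matrix(b, nrow = 1))
    wa$p
  }
  c(p_MPH = welch1(f1, mp), p_BPH = welch1(f1, bp))
}

#' Trait-level heterosis table
#'
#' Per trait: genotype means and standard deviations, MPH and BPH
#' percentages (rounded half-away-from-zero to 2 decimals in the `*_pct`
#' columns, unrounded in `*_raw`), and Welch-based significance.
#'
#' @param traits Long tibble with columns `trait`, `unit`, `genotype`,
#'   `replicate`, `value` (see [read_trait_table()]); all three genotypes
#'   and at least 2 replicates each per trait.
#' @return Tibble with one row per trait.
#' @export
heterosis_table <- function(traits) {
  traits <- tibble::as_tibble(traits)
  if (!all(.genotypes %in% unique(traits$genotype))) {
    abort("all three genotypes (P1, P2, F1) are required")
  }
  traits |>
    dplyr::group_by(.data$trait, .data$unit) |>
    dplyr::group_modify(function(d, key) {
      v <- split(d$value, d$genotype)
      sig <- heterosis_significance(v$P1, v$P2, v$F1)
      mph <- mid_parent_heterosis(v$P1, v$P2, v$F1)
      bph <- better_parent_heterosis(v$P1, v$P2, v$F1)
      tibble::tibble(
        mean_p1 = mean(v$P1), sd_p1 = sd(v$P1),
        mean_p2 = mean(v$P2), sd_p2 = sd(v$P2),
        mean_f1 = mean(v$F1), sd_f1 = sd(v$F1),
        mph_raw = mph, bph_raw = bph,
        mph_pct = round_half_away(mph, 2),
        bph_pct = round_half_away(bph, 2),
        p_mph = sig[["p_MPH"]], p_bph = sig[["p_BPH"]])
    }) |>
    dplyr::ungroup()
}
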