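#' Tidy a trio_result
#'
#' Returns one of the result tables as a tibble, broom-style.
#'
#' @param x A `trio_result` from [run_trio_pipeline()].
#' @param table Which table: `"inheritance"`, `"regulatory"`, `"ase"`,
#'   `"contrasts"`, or `"heterosis"`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.trio_result <- function(x, table = c("inheritance", "regulatory",
                                          "ase", "contrasts", "heterosis"),
                             ...) {
  table <- match.arg(table)
  out <- x[[table]]
  if (is.null(out)) {
    abort(sprintf("result has no '%s' table (stage not run)", table))
  }
  tibble::as_tibble(out)
}

#' One-row summary of a trio_result
#'
#' Per-stage headline numbers: classified genes, additive share, parental
#' dominance share among non-additive genes, SNP-qualified genes, ASE-gene
#' fraction, and cis-only / trans-only shares.
#'
#' @param x A `trio_result`.
#' @param ... Unused.
#' @return A tibble with one row per stage.
#' @exportS3Method generics::glance
glance.trio_result <- function(x, ...) {
  s <- x$inheritance_summary$summary
  base <- tibble::tibble(
    stage = s$stage, n_classified = s$n_total,
    additive_pct = 100 * s$n_additive / s$n_total,
    parental_dominance_share_pct = s$parental_dominance_share_pct)
  if (!is.null(x$ase)) {
    q_cut <- x$config$q_cutoff
    ase <- x$ase |>
      dplyr::group_by(.data$stage) |>
      dplyr::summarise(
        n_snp_qualified = dplyr::n(),
        ase_gene_pct = 100 * mean(.data$q < .env$q_cut & .data$bias != "none"),
        .groups = "drop")
    base <- dplyr::left_join(base, ase, by = "stage")
  }
  if (!is.null(x$regulatory)) {
    reg <- x$regulatory |>
      dplyr::group_by(.data$stage) |>
      dplyr::summarise(
        cis_only_pct = 100 * mean(.data$category == "cis_only"),
        trans_only_pct = 100 * mean(.data$category == "trans_only"),
        .groups = "drop")
    base <- dplyr::left_join(base, reg, by = "stage")
  }
  base
}
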