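#' Classify inheritance modes of F1 expression
#'
#' Applies the decision cascade per gene and stage, using the four contrast
#' q-values and the normalised parental means:
#'
#' 1. `q(F1_vs_MPV) >= q_cutoff` -> `additive` (F1 indistinguishable from
#'    the midparent value);
#' 2. else, F1 indistinguishable from the high-expressing parent but
#'    different from the low one -> `high_parent_dom`;
#' 3. else, the mirror case -> `low_parent_dom`;
#' 4. else, F1 significantly above both parents -> `overdominant`;
#'    significantly below both -> `underdominant`;
#' 5. anything left -> `unclassified` (reported, never dropped).
#'
#' When the parental means tie, the high/low parent is undefined and the
#' dominance rules are skipped. `dominant_parent` names the parent the F1
#' matches for dominance modes and is `"none"` otherwise.
#'
#' @param contrasts Tibble from [trio_contrasts()] for one stage (all four
#'   contrasts per gene).
#' @param q_cutoff Significance cutoff (default 0.05, strict).
#' @param lfc_cutoff DEG fold-change cutoff defining the default universe.
#' @param universe `"deg"` restricts the classification universe to genes
#'   flagged as DEGs in at least one of the four contrasts; `"all"` keeps
#'   every gene.
#' @return Tibble with `gene_id`, `stage`, `mode`, `dominant_parent`, the
#'   four q-values and log2 fold changes, and the parental means.
#' @export
classify_inheritance <- function(contrasts, q_cutoff = 0.05, lfc_cutoff = 1,
                                 universe = c("deg", "all")) {
  universe <- match.arg(universe)
  contrasts <- tibble::as_tibble(contrasts)
  got <- contrasts |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n < 4L)
  if (nrow(got)) {
    abort(sprintf("missing contrast(s) for gene(s): %s",
                  paste(utils::head(got$gene_id, 5), collapse = ", ")))
  }
  wide <- contrasts |>
    tidyr::pivot_wider(id_cols = c("gene_id", "stage", "mean_p1", "mean_p2"),
                       names_from = "contrast",
                       values_from = c("log2fc", "q"))
  if (universe == "deg") {
    degs <- call_degs(contrasts, lfc_cutoff, q_cutoff) |>
      dplyr::filter(.data$is_deg) |>
      dplyr::distinct(.data$gene_id)
    wide <- dplyr::semi_join(wide, degs, by = "gene_id")
  }

  q_mpv <- wide$q_F1_vs_MPV
  p1_is_high <- wide$mean_p1 > wide$mean_p2
  tie <- wide$mean_p1 == wide$mean_p2
  q_hi <- ifelse(p1_is_high, wide$q_F1_vs_P1, wide$q_F1_vs_P2)
  q_lo <- ifelse(p1_is_high, wide$q_F1_vs_P2, wide$q_F1_vs_P1)
  sig_p1 <- wide$q_F1_vs_P1 < q_cutoff
  sig_p2 <- wide$q_F1_vs_P2 < q_cutoff
  above_both <- sig_p1 & sig_p2 & wide$log2fc_F1_vs_P1 > 0 &
    wide$log2fc_F1_vs_P2 > 0
  below_both <- sig_p1 & sig_p2 & wide$log2fc_F1_vs_P1 < 0 &
    wide$log2fc_F1_vs_P2 < 0

  mode <- dplyr::case_when(
    q_mpv >= q_cutoff ~ "additive",
    !tie & q_hi >= q_cutoff & q_lo < q_cutoff ~ "high_parent_dom",
    !tie & q_lo >= q_cutoff & q_hi < q_cutoff ~ "low_parent_dom",
    above_both ~ "overdominant",
    below_both ~ "underdominant",
    TRUE ~ "unclassified")
  dominant_parent <- dplyr::case_when(
    mode == "high_parent_dom" & p1_is_high ~ "P1",
    mode == "high_parent_dom" ~ "P2",
    mode == "low_parent_dom" & p1_is_high ~ "P2",
    mode == "low_parent_dom" ~ "P1",
    TRUE ~ "none")

  wide |>
    dplyr::mutate(mode = mode, dominant_parent = dominant_parent) |>
    dplyr::relocate("mode", "dominant_parent", .after = "stage")
}

#' Tabulate inheritance patterns per stage
#'
#' Counts and percentages per mode, plus a per-stage summary: the share of
#' parental dominance among non-additive genes (everything not additive)
#' and the per-parent dominant-gene counts.
#'
#' @param calls Tibble from [classify_inheritance()] (one or more stages).
#' @return List with `modes` (stage, mode, n, pct) and `summary` (stage,
#'   n_total, n_additive, n_non_additive, n_dominance, dominant_p1,
#'   dominant_p2, n_overdominant, n_underdominant,
#'   parental_dominance_share_pct).
#' @export
tabulate_patterns <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (!nrow(calls)) {
    return(list(modes = tibble::tibble(stage = character(), mode = character(),
                                       n = integer(), pct = numeric()),
                summary = tibble::tibble()))
  }
  modes <- calls |>
    dplyr::count(.data$stage, .data$mode) |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  summary <- calls |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_additive = sum(.data$mode == "additive"),
      n_non_additive = sum(.data$mode != "additive"),
      n_dominance = sum(.data$mode %in% c("high_parent_dom", "low_parent_dom")),
      dominant_p1 = sum(.data$dominant_parent == "P1"),
      dominant_p2 = sum(.data$dominant_parent == "P2"),
      n_overdominant = sum(.data$mode == "overdominant"),
      n_underdominant = sum(.data$mode == "underdominant"),
      parental_dominance_share_pct =
        ifelse(n_non_additive > 0, 100 * n_dominance / n_non_additive,
               NA_real_),
      .groups = "drop")
  list(modes = modes, summary = summary)
}

#' Cross-stage transition of inheritance states
#'
#' Cross-tabulates each gene's state (`additive`, `non_additive`, `absent`)
#' between two stages over the union of their gene universes, and reports
#' retained/shifted fractions relative to each stage's classified
#' denominator.
#'
#' @param calls_an,calls_gf Tibbles from [classify_inheritance()] for the
#'   two stages.
#' @return List with `crosstab` (state_an, state_gf, n) and `summary`
#'   (denominators and retained/shifted fractions).
#' @export
stage_transition <- function(calls_an, calls_gf) {
  state_of <- function(calls, genes) {
    m <- setNames(ifelse(calls$mode == "additive", "additive", "non_additive"),
                  calls$gene_id)
    out <- m[genes]
    out[is.na(out)] <- "absent"
    unname(out)
  }
  genes <- union(calls_an$gene_id, calls_gf$gene_id)
  states <- c("additive", "non_additive", "absent")
  tab <- tibble::tibble(
    state_an = factor(state_of(calls_an, genes), levels = states),
    state_gf = factor(state_of(calls_gf, genes), levels = states)) |>
    dplyr::count(.data$state_an, .data$state_gf, .drop = FALSE)
  n_an <- sum(tab$n[tab$state_an != "absent"])
  n_gf <- sum(tab$n[tab$state_gf != "absent"])
  retained <- sum(tab$n[tab$state_an != "absent" &
                        as.character(tab$state_an) == as.character(tab$state_gf)])
  shifted_an <- sum(tab$n[tab$state_an != "absent" & tab$state_gf != "absent" &
                          as.character(tab$state_an) != as.character(tab$state_gf)])
  summary <- tibble::tibble(
    n_an = n_an, n_gf = n_gf, n_union = length(genes),
    retained_frac_an = ifelse(n_an > 0, retained / n_an, NA_real_),
    shifted_frac_an = ifelse(n_an > 0, shifted_an / n_an, NA_real_))
  list(crosstab = tab, summary = summary)
}
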