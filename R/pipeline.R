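#' Pipeline configuration
#'
#' Bundles every threshold the cascade uses and validates ranges before any
#' computation: probability cutoffs must lie in (0, 1), the ASE ratio
#' thresholds must be ordered `1 - ratio_pref < ratio_pref <= ratio_mono`.
#'
#' @param q_cutoff Significance cutoff (strict) for every test family.
#' @param lfc_cutoff DEG fold-change cutoff (inclusive), log2 units.
#' @param min_depth Minimum SNP-site read depth.
#' @param depth_tail Tail mass trimmed from the hybrid depth distribution.
#' @param ref_skew Maximum hybrid reference-allele skew.
#' @param ratio_mono,ratio_pref Allelic-ratio thresholds for monoallelic
#'   and preferential expression.
#' @param universe Inheritance classification universe (`"deg"` or
#'   `"all"`).
#' @param seed Integer seed recorded in output provenance.
#' @return Validated list of class `trio_config`.
#' @export
trio_config <- function(q_cutoff = 0.05, lfc_cutoff = 1, min_depth = 10,
                        depth_tail = 0.05, ref_skew = 2, ratio_mono = 0.95,
                        ratio_pref = 0.67, universe = c("deg", "all"),
                        seed = 1L) {
  universe <- match.arg(universe)
  if (!(q_cutoff > 0 && q_cutoff < 1)) abort("q_cutoff must be in (0, 1)")
  if (!(depth_tail >= 0 && depth_tail < 0.5)) {
    abort("depth_tail must be in [0, 0.5)")
  }
  if (lfc_cutoff < 0) abort("lfc_cutoff must be >= 0")
  if (min_depth < 1) abort("min_depth must be >= 1")
  if (!is.null(ref_skew) && ref_skew < 1) abort("ref_skew must be >= 1")
  if (!(ratio_pref > 0.5 && ratio_pref <= ratio_mono && ratio_mono < 1)) {
    abort("ASE ratio thresholds must satisfy 0.5 < ratio_pref <= ratio_mono < 1")
  }
  structure(list(q_cutoff = q_cutoff, lfc_cutoff = lfc_cutoff,
                 min_depth = min_depth, depth_tail = depth_tail,
                 ref_skew = ref_skew, ratio_mono = ratio_mono,
                 ratio_pref = ratio_pref, universe = universe,
                 seed = as.integer(seed)),
            class = "trio_config")
}

#' Run the full trio analysis cascade
#'
#' For each stage present in the data: the four expression contrasts,
#' inheritance-mode classification, SNP-site QC, gene-level ASE calling,
#' and the cis/trans regulatory decomposition; then the cross-stage
#' transition tables, the regulation-by-inheritance cross-tab, and (when a
#' trait table is given) the heterosis indices. With `out_dir` set, every
#' result table is written as a TSV with a provenance header plus a
#' `manifest.tsv` recording version, seed and config hash; identical input
#' and config give byte-identical outputs.
#'
#' @param counts A [trio_counts] object.
#' @param alleles Named list per stage, each a list of allele-count tables
#'   (`P1`, `P2`, `F1`) or file paths as accepted by
#'   [read_allele_counts()]. May be `NULL` to skip the allele-level arms.
#' @param gene_map Gene interval annotation (see [read_allele_counts()]).
#' @param traits Optional long trait table (see [heterosis_table()]).
#' @param config A [trio_config()].
#' @param out_dir Optional output directory for TSVs.
#' @return Object of class `trio_result`: a list with `contrasts`,
#'   `inheritance`, `inheritance_summary`, `stage_transition`, `ase`,
#'   `ase_stage_comparison`, `regulatory`, `divergence_summary`,
#'   `regulation_by_inheritance`, `heterosis`, `filter_logs`, `config`.
#' @export
run_trio_pipeline <- function(counts, alleles = NULL, gene_map = NULL,
                              traits = NULL, config = trio_config(),
                              out_dir = NULL) {
  stopifnot(inherits(counts, "trio_counts"), inherits(config, "trio_config"))
  stages <- intersect(.stages, unique(counts$samples$stage))
  sf <- size_factors(counts)

  contrasts <- purrr::map_dfr(stages, function(stg) {
    trio_contrasts(counts, stg, sf = sf)
  })
  inheritance <- purrr::map_dfr(stages, function(stg) {
    classify_inheritance(dplyr::filter(contrasts, .data$stage == stg),
                         q_cutoff = config$q_cutoff,
                         lfc_cutoff = config$lfc_cutoff,
                         universe = config$universe)
  })
  inh_tab <- tabulate_patterns(inheritance)
  transition <- if (length(stages) == 2) {
    stage_transition(dplyr::filter(inheritance, .data$stage == stages[1]),
                     dplyr::filter(inheritance, .data$stage == stages[2]))
  }

  ase <- NULL; regulatory <- NULL; filter_logs <- list()
  if (!is.null(alleles)) {
    per_stage <- lapply(stages, function(stg) {
      a <- alleles[[stg]]
      sites <- if (inherits(a, "allele_sites")) a
               else read_allele_counts(a$P1, a$P2, a$F1, gene_map)
      flt <- filter_sites(sites, min_depth = config$min_depth,
                          depth_tail = config$depth_tail,
                          ref_skew = config$ref_skew)
      gene_ase <- classify_ase(aggregate_gene_ase(flt$sites),
                               q_cutoff = config$q_cutoff,
                               ratio_mono = config$ratio_mono,
                               ratio_pref = config$ratio_pref)
      reg <- cistrans_calls(flt$sites, q_cutoff = config$q_cutoff,
                            min_depth = config$min_depth)
      list(stage = stg, ase = gene_ase, reg = reg,
           log = dplyr::bind_rows(attr(sites, "log"), flt$log))
    })
    names(per_stage) <- stages
    ase <- purrr::map_dfr(per_stage, function(s) {
      dplyr::mutate(s$ase, stage = s$stage, .after = "gene_id")
    })
    regulatory <- purrr::map_dfr(per_stage, function(s) {
      dplyr::mutate(tibble::as_tibble(s$reg), stage = s$stage,
                    .after = "gene_id")
    })
    filter_logs <- lapply(per_stage, `[[`, "log")
  }

  ase_cmp <- if (!is.null(ase) && length(stages) == 2) {
    compare_ase_stages(dplyr::filter(ase, .data$stage == stages[1]),
                       dplyr::filter(ase, .data$stage == stages[2]),
                       q_cutoff = config$q_cutoff)
  }
  div_summary <- if (!is.null(regulatory)) {
    lapply(setNames(stages, stages), function(stg) {
      summarize_divergence(dplyr::filter(regulatory, .data$stage == stg))
    })
  }
  reg_by_inh <- if (!is.null(regulatory)) {
    purrr::map_dfr(stages, function(stg) {
      tab <- cross_tab_regulation_inheritance(
        dplyr::filter(regulatory, .data$stage == stg),
        dplyr::filter(inheritance, .data$stage == stg))
      if (nrow(tab)) dplyr::mutate(tab, stage = stg, .before = 1) else tab
    })
  }
  het <- if (!is.null(traits)) heterosis_table(traits)

  res <- structure(list(
    contrasts = contrasts, inheritance = inheritance,
    inheritance_summary = inh_tab, stage_transition = transition,
    ase = ase, ase_stage_comparison = ase_cmp, regulatory = regulatory,
    divergence_summary = div_summary,
    regulation_by_inheritance = reg_by_inh, heterosis = het,
    filter_logs = filter_logs, config = config), class = "trio_result")

  if (!is.null(out_dir)) write_trio_result(res, out_dir)
  res
}

write_trio_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  hash <- rlang::hash(cfg)
  emit <- function(x, name) {
    if (!is.null(x) && nrow(tibble::as_tibble(x))) {
      write_trio_table(x, file.path(out_dir, name), seed = cfg$seed,
                       config_hash = hash)
    }
  }
  emit(res$contrasts, "contrasts.tsv")
  emit(res$inheritance, "inheritance_calls.tsv")
  emit(res$inheritance_summary$modes, "inheritance_modes.tsv")
  emit(res$inheritance_summary$summary, "inheritance_summary.tsv")
  if (!is.null(res$stage_transition)) {
    emit(res$stage_transition$crosstab, "stage_transition.tsv")
  }
  emit(res$ase, "ase_calls.tsv")
  if (!is.null(res$ase_stage_comparison)) {
    emit(res$ase_stage_comparison$crosstab, "ase_stage_crosstab.tsv")
  }
  emit(res$regulatory, "regulatory_calls.tsv")
  if (!is.null(res$divergence_summary)) {
    mag <- purrr::imap_dfr(res$divergence_summary, function(s, stg) {
      dplyr::mutate(s$magnitude, stage = stg, .before = 1)
    })
    emit(mag, "divergence_summary.tsv")
    bins <- purrr::imap_dfr(res$divergence_summary, function(s, stg) {
      dplyr::mutate(s$percent_cis_bins, stage = stg, .before = 1)
    })
    emit(bins, "percent_cis_bins.tsv")
  }
  emit(res$regulation_by_inheritance, "regulation_by_inheritance.tsv")
  emit(res$heterosis, "heterosis.tsv")
  manifest <- tibble::tibble(
    field = c("package", "version", "seed", "config_hash"),
    value = c("trioexpr", as.character(utils::packageVersion("trioexpr")),
              as.character(cfg$seed), hash))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' @export
print.trio_result <- function(x, ...) {
  cat("<trio_result>\n")
  if (!is.null(x$inheritance_summary$summary) &&
      nrow(x$inheritance_summary$summary)) {
    cat("inheritance (per stage):\n")
    print(x$inheritance_summary$summary)
  }
  if (!is.null(x$regulatory)) {
    cat("regulatory categories:\n")
    print(dplyr::count(x$regulatory, .data$stage, .data$category))
  }
  invisible(x)
}
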