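#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed from ratios to the per-gene
#' geometric mean reference, rescaled so their geometric mean is 1. Genes
#' with a zero count in any sample do not enter the reference. When no gene
#' is expressed in every sample the factors fall back to library-size
#' ratios, with a warning.
#'
#' @param x A [trio_counts] object or a count matrix.
#' @return Named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "trio_counts")) x$counts else as.matrix(x)
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    warn("no gene expressed in all samples; falling back to library-size ratios")
    libs <- colSums(counts)
    sf <- libs / exp(mean(log(libs)))
    return(sf)
  }
  logc <- log(counts[all_pos, , drop = FALSE])
  ref <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(median(col - ref)))
  sf / exp(mean(log(sf)))
}

#' FPKM matrix
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length[g] * library_size[s])`, with
#' library sizes taken as raw column sums.
#'
#' @param x A [trio_counts] object.
#' @param lengths Named numeric vector of transcript lengths in bases.
#' @return Numeric matrix of FPKM values, genes by samples.
#' @export
fpkm <- function(x, lengths) {
  stopifnot(inherits(x, "trio_counts"))
  missing_len <- setdiff(x$gene_ids, names(lengths))
  if (length(missing_len)) {
    abort(sprintf("missing length for gene(s): %s",
                  paste(utils::head(missing_len, 5), collapse = ", ")))
  }
  len <- lengths[x$gene_ids]
  libs <- x$samples$library_size
  sweep(x$counts * 1e9 / len, 2, libs, "/")
}

#' Expression-level bins from FPKM
#'
#' Per gene and stage, the replicate-mean FPKM over all samples of the
#' stage is binned: `< 1` not expressed, `[1, 20)` low, `[20, 50)`
#' moderate, `>= 50` high (boundaries inclusive on the left).
#'
#' @param fpkm_mat FPKM matrix from [fpkm()].
#' @param samples Sample metadata tibble (from a [trio_counts] object).
#' @return Tibble with `gene_id`, `stage`, `fpkm` (stage mean), `bin`.
#' @export
fpkm_bins <- function(fpkm_mat, samples) {
  if (any(fpkm_mat < 0)) abort("FPKM values must be non-negative")
  purrr::map_dfr(unique(samples$stage), function(stg) {
    cols <- samples$sample_id[samples$stage == stg]
    m <- rowMeans(fpkm_mat[, cols, drop = FALSE])
    tibble::tibble(gene_id = rownames(fpkm_mat), stage = stg, fpkm = m,
                   bin = dplyr::case_when(m < 1 ~ "not_expressed",
                                          m < 20 ~ "low",
                                          m < 50 ~ "moderate",
                                          TRUE ~ "high"))
  })
}

#' Midparent pseudo-samples
#'
#' Builds one pseudo-replicate per paired parental replicate: the mean of
#' the size-factor-normalised P1 and P2 counts, rounded to the nearest
#' integer so it can enter the same test engine as real samples. Replicates
#' are paired by sorted replicate index; unequal replicate numbers are
#' truncated to the smaller with a warning.
#'
#' @param x A [trio_counts] object.
#' @param stage Stage to use.
#' @param sf Size factors; computed from `x` when `NULL`.
#' @return Matrix of pseudo-sample columns named `MPV_<stage>_r<i>`, on the
#'   normalised count scale.
#' @export
make_midparent <- function(x, stage, sf = NULL) {
  stopifnot(inherits(x, "trio_counts"))
  sf <- sf %||% size_factors(x)
  norm <- sweep(x$counts, 2, sf, "/")
  smp <- x$samples
  p1 <- smp[smp$genotype == "P1" & smp$stage == stage, ]
  p2 <- smp[smp$genotype == "P2" & smp$stage == stage, ]
  p1 <- p1[order(p1$replicate), ]; p2 <- p2[order(p2$replicate), ]
  r <- min(nrow(p1), nrow(p2))
  if (nrow(p1) != nrow(p2)) {
    warn(sprintf("unequal parental replicate counts at %s; truncating to %d",
                 stage, r))
  }
  if (r == 0) abort(sprintf("no parental replicates at stage %s", stage))
  mpv <- round((norm[, p1$sample_id[seq_len(r)], drop = FALSE] +
                norm[, p2$sample_id[seq_len(r)], drop = FALSE]) / 2)
  colnames(mpv) <- sprintf("MPV_%s_r%d", stage, seq_len(r))
  mpv
}

#' Per-gene contrast test on normalised counts
#'
#' The built-in engine is a Welch two-sample test on
#' `log2(normalised count + 0.5)`; the log2 fold change is
#' `log2((mean(groupA) + 0.5) / (mean(groupB) + 0.5))` of the normalised
#' group means. Genes that are all-zero in both groups get `log2fc = 0`,
#' `p = 1`. q-values are BH-adjusted within the returned family.
#'
#' @param norm_a,norm_b Normalised count matrices (genes by replicates) for
#'   the two groups, identical rownames.
#' @return Tibble with `gene_id`, `log2fc` (A over B), `p`, `q`.
#' @export
test_contrast <- function(norm_a, norm_b) {
  stopifnot(identical(rownames(norm_a), rownames(norm_b)),
            ncol(norm_a) >= 2, ncol(norm_b) >= 2)
  w <- welch_rows(log2(norm_a + 0.5), log2(norm_b + 0.5))
  lfc <- log2((rowMeans(norm_a) + 0.5) / (rowMeans(norm_b) + 0.5))
  p <- w$p
  allzero <- rowSums(norm_a) == 0 & rowSums(norm_b) == 0
  lfc[allzero] <- 0
  p[allzero] <- 1
  tibble::tibble(gene_id = rownames(norm_a), log2fc = unname(lfc),
                 p = unname(p), q = bh_adjust(unname(p)))
}

#' The four trio contrasts for one stage
#'
#' Computes `F1_vs_MPV`, `F1_vs_P1`, `F1_vs_P2` and `P1_vs_P2` with the
#' built-in engine of [test_contrast()], or re-uses externally computed
#' per-gene `(log2fc, p)` tables (for example from a dedicated count-model
#' package) through `external`. In either case q-values are BH-adjusted
#' within each contrast and the normalised parental means are attached so
#' the inheritance classifier can identify the high- and low-expressing
#' parent.
#'
#' Fold changes read first-over-second: `F1_vs_P1` is `log2(F1 / P1)`.
#'
#' @param x A [trio_counts] object.
#' @param stage Stage to analyse.
#' @param sf Size factors; computed when `NULL`.
#' @param external Optional tibble `gene_id`, `contrast`, `log2fc`, `p`
#'   covering the four contrasts; the built-in engine is skipped.
#' @return Tibble with `gene_id`, `stage`, `contrast`, `log2fc`, `p`, `q`,
#'   `mean_p1`, `mean_p2` (normalised parental means, repeated per gene).
#' @export
trio_contrasts <- function(x, stage, sf = NULL, external = NULL) {
  stopifnot(inherits(x, "trio_counts"), stage %in% x$samples$stage)
  sf <- sf %||% size_factors(x)
  norm <- sweep(x$counts, 2, sf, "/")
  smp <- x$samples
  col_of <- function(geno) smp$sample_id[smp$genotype == geno & smp$stage == stage]
  groups <- list(F1 = norm[, col_of("F1"), drop = FALSE],
                 P1 = norm[, col_of("P1"), drop = FALSE],
                 P2 = norm[, col_of("P2"), drop = FALSE],
                 MPV = make_midparent(x, stage, sf))
  means <- tibble::tibble(gene_id = rownames(norm),
                          mean_p1 = rowMeans(groups$P1),
                          mean_p2 = rowMeans(groups$P2))

  if (!is.null(external)) {
    external <- tibble::as_tibble(external)
    missing_ctr <- setdiff(.contrast_names, unique(external$contrast))
    if (length(missing_ctr)) {
      abort(sprintf("external results lack contrast(s): %s",
                    paste(missing_ctr, collapse = ", ")))
    }
    res <- external |>
      dplyr::filter(.data$contrast %in% .contrast_names) |>
      dplyr::group_by(.data$contrast) |>
      dplyr::mutate(q = bh_adjust(.data$p)) |>
      dplyr::ungroup()
  } else {
    pairs <- list(F1_vs_MPV = c("F1", "MPV"), F1_vs_P1 = c("F1", "P1"),
                  F1_vs_P2 = c("F1", "P2"), P1_vs_P2 = c("P1", "P2"))
    res <- purrr::imap_dfr(pairs, function(gr, nm) {
      dplyr::mutate(test_contrast(groups[[gr[1]]], groups[[gr[2]]]),
                    contrast = nm, .after = "gene_id")
    })
  }
  res |>
    dplyr::mutate(stage = stage, .after = "gene_id") |>
    dplyr::left_join(means, by = "gene_id")
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG under a contrast iff `|log2fc| >= lfc_cutoff`
#' (inclusive) and `q < q_cutoff` (strict).
#'
#' @param contrasts Tibble from [trio_contrasts()] or [test_contrast()].
#' @param lfc_cutoff,q_cutoff Thresholds (defaults 1 and 0.05).
#' @return The input with a logical `is_deg` column.
#' @export
call_degs <- function(contrasts, lfc_cutoff = 1, q_cutoff = 0.05) {
  dplyr::mutate(tibble::as_tibble(contrasts),
                is_deg = abs(.data$log2fc) >= lfc_cutoff & .data$q < q_cutoff)
}
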