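#' Construct a validated trio count object
#'
#' Bundles a gene-by-sample integer count matrix with its sample metadata.
#' Genotypes are restricted to `P1`, `P2`, `F1` and stages to `AN`
#' (anthesis) and `GF` (grain filling); library sizes are always recomputed
#' as column sums.
#'
#' @param counts Integer matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids).
#' @param samples Data frame with columns `sample_id`, `genotype`, `stage`,
#'   `replicate`, one row per column of `counts`.
#' @return An object of class `trio_counts`: a list with elements `counts`
#'   (integer matrix), `samples` (tibble including `library_size`), and
#'   `gene_ids`.
#' @export
trio_counts <- function(counts, samples) {
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "genotype", "stage", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    abort(paste0("sample metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have gene ids as rownames and sample ids as colnames")
  }
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "counts must be non-negative integers; first offender gene '%s', sample '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])))
  }
  if (anyDuplicated(rownames(counts))) {
    abort(sprintf("duplicate gene id: '%s'",
                  rownames(counts)[anyDuplicated(rownames(counts))]))
  }
  absent <- setdiff(colnames(counts), samples$sample_id)
  if (length(absent)) {
    abort(sprintf("sample(s) in matrix absent from metadata: %s",
                  paste(absent, collapse = ", ")))
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (!all(samples$genotype %in% .genotypes)) {
    abort("genotype must be one of P1, P2, F1")
  }
  if (!all(samples$stage %in% .stages)) {
    abort("stage must be one of AN, GF")
  }
  if (anyDuplicated(samples[, c("genotype", "stage", "replicate")])) {
    abort("each (genotype, stage, replicate) triple must be unique")
  }
  samples$replicate <- as.integer(samples$replicate)
  samples$library_size <- unname(colSums(counts))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples,
                 gene_ids = rownames(counts)),
            class = "trio_counts")
}

#' @export
print.trio_counts <- function(x, ...) {
  cat(sprintf("<trio_counts> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(dplyr::count(x$samples, .data$genotype, .data$stage))
  invisible(x)
}

#' Read a gene-by-sample count matrix with sample metadata
#'
#' The matrix TSV has a header of sample ids and gene ids in the first
#' column; the metadata TSV maps each sample id to its genotype, stage and
#' replicate. Cells must be non-negative integers: a fractional or negative
#' value fails with a message naming the offending gene and sample.
#'
#' @param path Count matrix TSV.
#' @param metadata_path Sample metadata TSV (`sample_id`, `genotype`,
#'   `stage`, `replicate`).
#' @return A [trio_counts] object.
#' @export
read_count_matrix <- function(path, metadata_path) {
  mat_df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  gene_ids <- as.character(mat_df[[1]])
  num <- mat_df[-1]
  for (j in names(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad)) {
      abort(sprintf("non-numeric count for gene '%s', sample '%s': %s",
                    gene_ids[bad[1]], j, format(num[[j]][bad[1]])))
    }
    num[[j]] <- v
  }
  counts <- as.matrix(num)
  rownames(counts) <- gene_ids
  samples <- readr::read_tsv(metadata_path, comment = "#",
                             show_col_types = FALSE)
  trio_counts(counts, samples)
}

#' Read per-SNP allele counts for the two parents and the hybrid
#'
#' Each file is an ASEReadCounter-style TSV with columns `contig`,
#' `position` (1-based), `refAllele`, `altAllele`, `refCount`, `altCount`.
#' Sites are joined across the three roles on (contig, position), assigned
#' to genes by the interval annotation, and the hybrid's ref/alt counts are
#' re-labelled to parental alleles. Indel records (alleles longer than one
#' base), sites missing from a parent, sites where the parents do not carry
#' different consensus bases, and sites outside every gene are dropped and
#' tallied in the rejection log (attribute `"log"`).
#'
#' The parent carrying the reference base is inferred from the parental
#' counts: the parent whose reads support the reference allele more
#' strongly is `parent_of_ref`.
#'
#' @param p1_path,p2_path,hybrid_path Allele-count TSVs for the P1 sample,
#'   P2 sample, and hybrid.
#' @param gene_map Data frame (or BED-like TSV path) with columns `contig`,
#'   `start`, `end`, `gene_id`; intervals are 1-based and inclusive.
#' @return Tibble of class `allele_sites` with one row per retained site:
#'   `contig`, `position`, `gene_id`, `ref_allele`, `alt_allele`,
#'   `parent_of_ref`, `count_p1_sample`, `count_p2_sample`,
#'   `hybrid_count_p1_allele`, `hybrid_count_p2_allele`. The rejection log
#'   (tibble of `reason`, `n`) is attached as attribute `"log"`.
#' @export
read_allele_counts <- function(p1_path, p2_path, hybrid_path, gene_map) {
  read_one <- function(path) {
    if (is.data.frame(path)) tibble::as_tibble(path)
    else readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  }
  p1 <- read_one(p1_path); p2 <- read_one(p2_path); hy <- read_one(hybrid_path)
  if (is.character(gene_map)) gene_map <- read_gene_map(gene_map)
  gene_map <- tibble::as_tibble(gene_map)
  n_total <- nrow(hy)
  log <- list()

  indel <- nchar(hy$refAllele) != 1L | nchar(hy$altAllele) != 1L
  log$indel <- sum(indel)
  hy <- hy[!indel & hy$refAllele != hy$altAllele, ]
  log$identical_alleles <- n_total - log$indel - nrow(hy)

  key <- function(d) paste(d$contig, d$position)
  in_p1 <- key(hy) %in% key(p1)
  in_p2 <- key(hy) %in% key(p2)
  log$missing_in_parent <- sum(!(in_p1 & in_p2))
  hy <- hy[in_p1 & in_p2, ]
  p1 <- p1[match(key(hy), key(p1)), ]
  p2 <- p2[match(key(hy), key(p2)), ]

  # parent-of-reference from parental consensus; parents must disagree
  frac_ref_p1 <- ifelse(p1$refCount + p1$altCount > 0,
                        p1$refCount / (p1$refCount + p1$altCount), 0.5)
  frac_ref_p2 <- ifelse(p2$refCount + p2$altCount > 0,
                        p2$refCount / (p2$refCount + p2$altCount), 0.5)
  informative <- (frac_ref_p1 > 0.5 & frac_ref_p2 < 0.5) |
                 (frac_ref_p1 < 0.5 & frac_ref_p2 > 0.5)
  log$not_parent_informative <- sum(!informative)
  hy <- hy[informative, ]; p1 <- p1[informative, ]; p2 <- p2[informative, ]
  parent_of_ref <- ifelse(frac_ref_p1[informative] > 0.5, "P1", "P2")

  sites <- tibble::tibble(
    contig = hy$contig, position = hy$position,
    ref_allele = hy$refAllele, alt_allele = hy$altAllele,
    parent_of_ref = parent_of_ref,
    # each parent's reads supporting its own consensus allele
    count_p1_sample = ifelse(parent_of_ref == "P1", p1$refCount, p1$altCount),
    count_p2_sample = ifelse(parent_of_ref == "P2", p2$refCount, p2$altCount),
    hybrid_count_p1_allele = ifelse(parent_of_ref == "P1",
                                    hy$refCount, hy$altCount),
    hybrid_count_p2_allele = ifelse(parent_of_ref == "P2",
                                    hy$refCount, hy$altCount))

  sites$gene_id <- assign_genes(sites$contig, sites$position, gene_map)
  log$outside_genes <- sum(is.na(sites$gene_id))
  sites <- sites[!is.na(sites$gene_id), ]
  sites <- dplyr::relocate(sites, "gene_id", .after = "position")

  log_tbl <- tibble::tibble(reason = names(log), n = unlist(log, use.names = FALSE))
  stopifnot(nrow(sites) + sum(log_tbl$n) == n_total)
  attr(sites, "log") <- log_tbl
  class(sites) <- c("allele_sites", class(sites))
  sites
}

# Map positions to gene ids. Fast findInterval path per contig when the
# intervals do not overlap; overlapping annotations fall back to a scan and
# take the interval with the smallest start.
assign_genes <- function(contig, position, gene_map) {
  out <- rep(NA_character_, length(position))
  for (ctg in unique(contig)) {
    gm <- gene_map[gene_map$contig == ctg, ]
    sel <- which(contig == ctg)
    if (!nrow(gm)) next
    gm <- gm[order(gm$start, gm$end), ]
    overlapping <- nrow(gm) > 1 && any(gm$start[-1] <= cummax(gm$end)[-nrow(gm)])
    if (!overlapping) {
      idx <- findInterval(position[sel], gm$start)
      ok <- idx >= 1 & ifelse(idx >= 1, position[sel] <= gm$end[pmax(idx, 1)], FALSE)
      out[sel[ok]] <- gm$gene_id[idx[ok]]
    } else {
      out[sel] <- vapply(position[sel], function(p) {
        hit <- which(gm$start <= p & gm$end >= p)
        if (!length(hit)) NA_character_ else gm$gene_id[hit[1]]
      }, character(1))
    }
  }
  out
}

#' Read a BED-like gene interval annotation
#'
#' @param path TSV with columns `contig`, `start`, `end`, `gene_id`
#'   (1-based, inclusive intervals).
#' @return Tibble with those columns.
#' @export
read_gene_map <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_names = c("contig", "start", "end", "gene_id"))
}

#' Read a gene length table for FPKM
#'
#' @param path TSV with columns `gene_id`, `length` (bases, positive).
#' @return Named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (any(tbl$length <= 0)) abort("gene lengths must be positive")
  setNames(tbl$length, tbl$gene_id)
}

#' Read a trait replicate table
#'
#' @param path CSV with columns `trait`, `unit`, `genotype`, `replicate`,
#'   `value`.
#' @return Tibble of trait measurements.
#' @export
read_trait_table <- function(path) {
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(tbl$genotype %in% .genotypes)) {
    abort("trait genotype must be one of P1, P2, F1")
  }
  tbl
}

#' Write a result table with a provenance header
#'
#' Emits a TSV preceded by `#`-comment lines recording the package version
#' and, when supplied, a configuration hash and the seed, so outputs are
#' diffable and traceable. Column order is preserved as given.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param seed,config_hash Optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_trio_table <- function(x, path, seed = NULL, config_hash = NULL) {
  header <- c(
    sprintf("# trioexpr %s", as.character(utils::packageVersion("trioexpr"))),
    if (!is.null(config_hash)) sprintf("# config_hash: %s", config_hash),
    if (!is.null(seed)) sprintf("# seed: %s", format(seed)))
  writeLines(header, path)
  readr::write_tsv(tibble::as_tibble(x), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Read a table written by [write_trio_table()]
#'
#' @param path TSV path; `#` header lines are skipped.
#' @return Tibble.
#' @export
read_trio_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
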