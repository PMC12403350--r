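#' Bar chart of inheritance modes per stage
#'
#' @param calls Tibble from [classify_inheritance()].
#' @return A ggplot object.
#' @export
plot_inheritance <- function(calls) {
  ggplot2::ggplot(tibble::as_tibble(calls),
                  ggplot2::aes(x = .data$mode, fill = .data$stage)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "inheritance mode", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bar chart of regulatory categories per stage
#'
#' @param calls Tibble from [cistrans_calls()] (with a `stage` column).
#' @return A ggplot object.
#' @export
plot_regulation <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (!"stage" %in% names(calls)) calls$stage <- "all"
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$category, fill = .data$stage)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "regulatory category", y = "genes", fill = "stage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Percent-cis by divergence-magnitude bin
#'
#' @param bins Tibble `percent_cis_bins` from [summarize_divergence()].
#' @return A ggplot object.
#' @export
plot_percent_cis <- function(bins) {
  ggplot2::ggplot(tibble::as_tibble(bins),
                  ggplot2::aes(x = factor(.data$bin),
                               y = .data$mean_percent_cis)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "|P| bin (log2 units, upper edge)",
                  y = "mean % cis") +
    ggplot2::theme_minimal()
}

#' Autoplot method for trio_result
#'
#' @param object A `trio_result`.
#' @param type `"inheritance"`, `"regulation"`, or `"percent_cis"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trio_result <- function(object, type = c("inheritance",
                                                  "regulation",
                                                  "percent_cis"), ...) {
  type <- match.arg(type)
  switch(type,
    inheritance = plot_inheritance(object$inheritance),
    regulation = plot_regulation(object$regulatory),
    percent_cis = {
      bins <- purrr::imap_dfr(object$divergence_summary, function(s, stg) {
        dplyr::mutate(s$percent_cis_bins, stage = stg)
      })
      plot_percent_cis(bins) + ggplot2::facet_wrap(~stage)
    })
}
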