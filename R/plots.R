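# ggplot2 displays for the main result types.

#' Heatmap of expression summaries
#'
#' Tile heatmap of either absolute (log10) or relative (per-gene Z-score)
#' accumulation across samples, the standard twin display for family-wide
#' expression atlases.
#'
#' @param object A `pap_expression` tibble from [summarize_expression()].
#' @param value `"zscore"` (default) or `"log10_value"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pap_expression <- function(object, value = c("zscore",
                                                      "log10_value"), ...) {
  value <- match.arg(value)
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$sample, y = .data$gene_id, fill = .data[[value]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b",
      midpoint = if (value == "zscore") 0 else
        stats::median(object[[value]])
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = if (value == "zscore")
      "Z-score" else "log10") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Fold-change plot for differential-accumulation calls
#'
#' @param object A `pap_de` tibble from [test_differential()].
#' @param ... Unused.
#' @return A ggplot object: per-gene log2 fold-change, significant calls
#'   highlighted, faceted by tissue.
#' @export
autoplot.pap_de <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$log2fc, y = .data$gene_id, fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$tissue)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "log2 fold-change (-P / +P)", y = NULL,
                  fill = "adj. p < alpha") +
    ggplot2::theme_minimal()
}

#' Map of cis-element locations upstream of each gene
#'
#' @param object A `pap_p1bs` table from [tabulate_p1bs()] or
#'   [read_p1bs_reference()].
#' @param window Upstream window to display (bp).
#' @param ... Unused.
#' @return A ggplot object: one row per gene, a point per element.
#' @export
autoplot.pap_p1bs <- function(object, window = 2500, ...) {
  pts <- object |>
    dplyr::mutate(gene_id = factor(.data$gene_id,
                                   levels = rev(.data$gene_id))) |>
    tidyr::unnest_longer("locations", values_to = "offset",
                         keep_empty = FALSE)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$offset, y = .data$gene_id)) +
    ggplot2::geom_point(shape = 18, size = 3, colour = "#b2182b") +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::xlim(-window, 0) +
    ggplot2::labs(x = "position relative to anchor (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Information-content profile of a scoring model
#'
#' @param object A `pap_profile`.
#' @param ... Unused.
#' @return A ggplot object: per-match-column relative entropy (bits).
#' @export
autoplot.pap_profile <- function(object, ...) {
  lo <- tidy(object)
  ic <- lo |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(bits = sum(pmax(.data$log_odds, 0) *
                                  2^.data$log_odds / 20))
  ggplot2::ggplot(ic, ggplot2::aes(x = .data$column, y = .data$bits)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "match column", y = "information (bits)") +
    ggplot2::theme_minimal()
}
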