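# ggplot2 views of the main result types.

#' Tail-length "volcano": adjusted p against median tail-length change
#'
#' @param tails Tibble from [differential_adenylation()].
#' @param alpha,delta_threshold Dashed guide lines (the dual significance
#'   rule).
#' @return A ggplot.
#' @export
plot_tail_volcano <- function(tails, alpha = 0.05, delta_threshold = 5) {
  ggplot2::ggplot(tails, ggplot2::aes(x = .data$delta_median,
                                      y = -log10(.data$p_adj),
                                      colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "pink3") +
    ggplot2::geom_vline(xintercept = c(-delta_threshold, delta_threshold),
                        linetype = "dashed", colour = "pink3") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "maroon")) +
    ggplot2::labs(x = "Δ median tail length (stimulated - control, nt)",
                  y = "-log10 adjusted p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Expression change against tail-length change
#'
#' @param de Differential-expression tibble.
#' @param tails Differential-adenylation tibble.
#' @param transcripts Optional annotation for the transcript -> gene map.
#' @param significant_tails_only Restrict to significant tail changes.
#' @return A ggplot.
#' @export
plot_expression_adenylation <- function(de, tails, transcripts = NULL,
                                        significant_tails_only = TRUE) {
  tg <- tails
  if (!is.null(transcripts)) {
    map <- stats::setNames(transcripts$gene_id, transcripts$transcript_id)
    tg$gene_id <- unname(map[tails$transcript_id])
  } else {
    tg$gene_id <- tails$transcript_id
  }
  if (significant_tails_only) tg <- tg[tg$significant, , drop = FALSE]
  joined <- dplyr::inner_join(de[, c("gene_id", "log2_fc", "significant")],
                              tg[, c("gene_id", "delta_mean")], by = "gene_id")
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$log2_fc, y = .data$delta_mean,
                                       colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "maroon")) +
    ggplot2::labs(x = "log2 fold change (expression)",
                  y = "Δ mean tail length (nt)",
                  colour = "DE significant") +
    ggplot2::theme_minimal()
}

#' Decoration rate by tail-length bin
#'
#' @param composition Tibble from [composition_summary()].
#' @return A ggplot.
#' @export
plot_decoration_by_length <- function(composition) {
  prof <- composition |>
    dplyr::select("scope", "rate_by_length") |>
    tidyr::unnest("rate_by_length")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$bin_lo + 10,
                                     y = .data$frac_decorated,
                                     group = .data$scope)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_reads), alpha = 0.6) +
    ggplot2::labs(x = "tail length bin midpoint (nt)",
                  y = "fraction of decorated tails", size = "reads") +
    ggplot2::theme_minimal()
}

#' Hexamer offset profile upstream of PAS anchors
#'
#' @param hexamers Tibble from [hexamer_enrichment()].
#' @return A ggplot.
#' @export
plot_hexamer_profile <- function(hexamers) {
  ggplot2::ggplot(hexamers, ggplot2::aes(x = .data$offset, y = .data$n,
                                         fill = .data$hexamer)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "hexamer start offset from PAS anchor (nt)",
                  y = "occurrences", fill = "hexamer") +
    ggplot2::theme_minimal()
}

#' Mechanism label counts
#'
#' @param mechanisms Tibble from [classify_mechanism()].
#' @return A ggplot.
#' @export
plot_mechanism_counts <- function(mechanisms) {
  counts <- dplyr::count(mechanisms, .data$label)
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$label, .data$n),
                                       y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}
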