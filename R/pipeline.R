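# Orchestration and mechanism discrimination: joins the expression and
# adenylation results to label each gene's 3'-end behaviour, and provides
# the expression--adenylation correlation.

#' Pearson correlation with t-test
#'
#' Product-moment correlation with `t = r * sqrt((n - 2) / (1 - r^2))`,
#' `df = n - 2`, and a two-sided p-value from Student's t. Perfect
#' correlation reports `t = +/-Inf` and `p = 0`.
#'
#' @param x,y Finite numeric vectors, `n >= 3`.
#' @return Object of class `tailscape_cor`: `n`, `r`, `t_stat`, `df`,
#'   `p_two_sided`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate input: zero variance")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  df <- n - 2L
  if (abs(r) >= 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(n = n, r = r, t_stat = t_stat, df = df, p_two_sided = p),
            class = "tailscape_cor")
}

#' @export
print.tailscape_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f (n = %d, t = %.3f, df = %d, p = %.3g)\n",
              x$r, x$n, x$t_stat, x$df, x$p_two_sided))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correlation result
#'
#' @param x A `tailscape_cor`.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `statistic`, `p.value`, `parameter`,
#'   `n`.
#' @exportS3Method generics::tidy
tidy.tailscape_cor <- function(x, ...) {
  tibble::tibble(estimate = x$r, statistic = x$t_stat, p.value = x$p_two_sided,
                 parameter = x$df, n = x$n)
}

#' @rdname tidy.tailscape_cor
#' @exportS3Method generics::glance
glance.tailscape_cor <- function(x, ...) tidy(x)

#' Label the 3'-end mechanism of each gene
#'
#' Joins per-gene differential expression and per-transcript differential
#' adenylation, derives `expr_state` (up/down/unchanged from the
#' significance flag and the fold-change sign) and `tail_state`
#' (elongated/shortened/unchanged from the significance flag and the median
#' delta sign), and maps the pair to a mechanism label: up + elongated ->
#' `transcriptional_induction`; unchanged + elongated ->
#' `cytoplasmic_polyadenylation_candidate`; down + shortened ->
#' `deadenylation_decay`; unchanged or up + shortened ->
#' `translation_deadenylation_like`; anything else -> `stable`. Genes absent
#' from one analysis get the `unchanged` state on that axis and are flagged
#' in `in_both`.
#'
#' @param de Tibble from [nb_wald_test()] / [differential_expression()].
#' @param tails Tibble from [differential_adenylation()].
#' @param transcripts Optional annotation to map transcript results to genes
#'   (without it the transcript id is taken as the gene id).
#' @return Tibble: `gene_id`, `expr_state`, `tail_state`, `label`,
#'   `in_both`.
#' @export
classify_mechanism <- function(de, tails, transcripts = NULL) {
  tail_gene <- tails
  if (!is.null(transcripts)) {
    map <- stats::setNames(transcripts$gene_id, transcripts$transcript_id)
    tail_gene$gene_id <- unname(map[tails$transcript_id])
  } else {
    tail_gene$gene_id <- tails$transcript_id
  }
  joined <- dplyr::full_join(
    de[, c("gene_id", "log2_fc", "significant")],
    tail_gene[, c("gene_id", "delta_median", "significant")],
    by = "gene_id", suffix = c("_expr", "_tail"))
  joined |>
    dplyr::mutate(
      in_both = !is.na(.data$significant_expr) & !is.na(.data$significant_tail),
      expr_state = dplyr::case_when(
        is.na(.data$significant_expr) | !.data$significant_expr ~ "unchanged",
        .data$log2_fc > 0 ~ "up",
        TRUE ~ "down"),
      tail_state = dplyr::case_when(
        is.na(.data$significant_tail) | !.data$significant_tail ~ "unchanged",
        .data$delta_median > 0 ~ "elongated",
        TRUE ~ "shortened"),
      label = dplyr::case_when(
        .data$expr_state == "up" & .data$tail_state == "elongated" ~
          "transcriptional_induction",
        .data$expr_state == "unchanged" & .data$tail_state == "elongated" ~
          "cytoplasmic_polyadenylation_candidate",
        .data$expr_state == "down" & .data$tail_state == "shortened" ~
          "deadenylation_decay",
        .data$expr_state %in% c("unchanged", "up") & .data$tail_state == "shortened" ~
          "translation_deadenylation_like",
        TRUE ~ "stable")) |>
    dplyr::select("gene_id", "expr_state", "tail_state", "label", "in_both")
}

#' Correlate expression change with adenylation change
#'
#' Pearson test of `log2_fc` against `delta_mean` over genes present in both
#' analyses, optionally restricted to genes with a significant tail change
#' (the default, mirroring how such joint displays are usually filtered).
#'
#' @param de Differential-expression tibble.
#' @param tails Differential-adenylation tibble.
#' @param transcripts Optional annotation for the transcript -> gene map.
#' @param significant_tails_only Restrict to significant tail changes.
#' @return A `tailscape_cor`.
#' @export
correlate_expression_adenylation <- function(de, tails, transcripts = NULL,
                                             significant_tails_only = TRUE) {
  tg <- tails
  if (!is.null(transcripts)) {
    map <- stats::setNames(transcripts$gene_id, transcripts$transcript_id)
    tg$gene_id <- unname(map[tails$transcript_id])
  } else {
    tg$gene_id <- tails$transcript_id
  }
  if (significant_tails_only) tg <- tg[tg$significant, , drop = FALSE]
  joined <- dplyr::inner_join(de[, c("gene_id", "log2_fc")],
                              tg[, c("gene_id", "delta_mean")], by = "gene_id")
  if (nrow(joined) < 3L) stop("fewer than 3 genes present in both analyses")
  pearson_test(joined$log2_fc, joined$delta_mean)
}

#' Run the full analysis pipeline
#'
#' Either simulates a dataset (when `data` is `NULL`) or consumes a list
#' with `reads`, `transcripts` and `genome`, then runs differential
#' adenylation, differential expression, PAS calling + differential usage +
#' hexamer profiling, CPE annotation (when motifs are supplied),
#' semi-templated calling, mechanism discrimination and the
#' expression--adenylation correlation.
#'
#' @param config A [sim_config()] (used when `data` is `NULL`).
#' @param data Optional list with `reads`, `transcripts`, `genome` (and
#'   optionally `truth`).
#' @param motifs Optional motif list for CPE annotation.
#' @param tail_config,apa_cfg,semi_config Stage configurations.
#' @return A list of class `tailscape_report` with per-stage tibbles, the
#'   mechanism table, the correlation block and per-stage counts.
#' @export
run_tailscape <- function(config = sim_config(), data = NULL, motifs = NULL,
                          tail_config = tail_test_config(),
                          apa_cfg = apa_config(),
                          semi_config = semitemplated_config()) {
  if (is.null(data)) data <- simulate_dataset(config)
  reads <- data$reads
  transcripts <- data$transcripts
  genome <- data$genome

  tails <- differential_adenylation(reads, tail_config)
  de <- differential_expression(reads, transcripts)
  composition <- composition_summary(reads)

  clusters <- cluster_read_ends(reads, transcripts, apa_cfg)
  clusters <- assign_pas_features(clusters, transcripts)
  cmx <- count_matrix(filter_qc(reads), transcripts)
  sf <- size_factors(cmx$counts)
  usage <- differential_pas_usage(clusters, apa_cfg, sf = sf)
  shifts <- proximal_distal_shift(clusters, sf = sf)
  hexamers <- hexamer_enrichment(clusters, genome, apa_cfg)

  cpe <- if (!is.null(motifs)) annotate_cpe(transcripts, genome, motifs) else NULL

  windows <- candidate_windows(transcripts, genome, clusters, semi_config)
  semi <- call_semitemplated(windows, reads, semi_config)

  mechanisms <- classify_mechanism(de, tails, transcripts)
  correlation <- tryCatch(
    correlate_expression_adenylation(de, tails, transcripts),
    error = function(e) NULL)

  report <- list(
    tails = tails, expression = de, composition = composition,
    pas_clusters = clusters, pas_usage = usage, pas_shifts = shifts,
    hexamers = hexamers, cpe = cpe, semitemplated = semi,
    mechanisms = mechanisms, correlation = correlation,
    truth = data$truth,
    counts = list(
      n_reads = nrow(reads),
      n_transcripts_tested = nrow(tails),
      n_tail_significant = sum(tails$significant),
      n_genes_de = sum(de$significant),
      n_pas = nrow(clusters),
      n_pas_differential = sum(usage$differential),
      semitemplated_sets = attr(semi, "set_sizes"),
      mechanism_table = table(mechanisms$label)))
  class(report) <- "tailscape_report"
  report
}

#' @export
print.tailscape_report <- function(x, ...) {
  cat("tailscape report\n")
  cat("  reads:                 ", x$counts$n_reads, "\n")
  cat("  transcripts tested:    ", x$counts$n_transcripts_tested, "\n")
  cat("  significant tails:     ", x$counts$n_tail_significant, "\n")
  cat("  differential genes:    ", x$counts$n_genes_de, "\n")
  cat("  PAS clusters:          ", x$counts$n_pas,
      " (differential:", x$counts$n_pas_differential, ")\n")
  cat("  semi-templated called: ",
      unname(x$counts$semitemplated_sets["called"]), "\n")
  if (!is.null(x$correlation)) {
    cat("  expression ~ tail r:   ", sprintf("%.3f", x$correlation$r), "\n")
  }
  invisible(x)
}

#' Tidy a pipeline report (mechanism labels per gene)
#'
#' @param x A `tailscape_report`.
#' @param ... Unused.
#' @return The per-gene mechanism tibble.
#' @exportS3Method generics::tidy
tidy.tailscape_report <- function(x, ...) x$mechanisms

#' One-row summary of a pipeline report
#'
#' @param x A `tailscape_report`.
#' @param ... Unused.
#' @return One-row tibble of headline counts.
#' @exportS3Method generics::glance
glance.tailscape_report <- function(x, ...) {
  tibble::tibble(
    n_reads = x$counts$n_reads,
    n_transcripts_tested = x$counts$n_transcripts_tested,
    n_tail_significant = x$counts$n_tail_significant,
    n_genes_de = x$counts$n_genes_de,
    n_pas = x$counts$n_pas,
    n_pas_differential = x$counts$n_pas_differential,
    n_semitemplated = unname(x$counts$semitemplated_sets["called"]),
    correlation_r = if (is.null(x$correlation)) NA_real_ else x$correlation$r,
    correlation_p = if (is.null(x$correlation)) NA_real_ else x$correlation$p_two_sided)
}

#' Write the tabular pieces of a report to a directory
#'
#' TSVs per stage plus a JSON block of counts; byte-identical across runs
#' with the same configuration and seed.
#'
#' @param report A `tailscape_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- function(x, f) readr::write_tsv(x, file.path(dir, f), progress = FALSE)
  out(report$tails, "tails.tsv")
  out(report$expression, "expression.tsv")
  out(report$mechanisms, "mechanisms.tsv")
  out(dplyr::select(report$pas_clusters, -"support_by_sample"), "pas_clusters.tsv")
  out(report$pas_usage, "pas_usage.tsv")
  out(dplyr::select(report$semitemplated, dplyr::where(~!is.list(.x))),
      "semitemplated.tsv")
  counts <- report$counts
  counts$mechanism_table <- as.list(counts$mechanism_table)
  counts$semitemplated_sets <- as.list(counts$semitemplated_sets)
  if (!is.null(report$correlation)) {
    counts$correlation <- unclass(report$correlation)
  }
  jsonlite::write_json(counts, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
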