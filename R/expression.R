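# Gene-level count-based differential expression: a deliberately simplified
# negative-binomial Wald test (median-of-ratios normalization, per-gene
# moment dispersion, delta-method standard error). No dispersion shrinkage
# and no LFC shrinkage.

#' Gene x sample count matrix from read records
#'
#' @param reads Per-read tibble (QC-filtered by the caller if desired).
#' @param transcripts Optional annotation tibble mapping transcript to gene;
#'   without it the transcript id is used as the gene id.
#' @return List with `counts` (integer matrix, genes x samples) and
#'   `conditions` (named character vector sample -> condition).
#' @export
count_matrix <- function(reads, transcripts = NULL) {
  gene <- if (is.null(transcripts)) reads$transcript_id else {
    map <- stats::setNames(transcripts$gene_id, transcripts$transcript_id)
    unname(map[reads$transcript_id])
  }
  tab <- table(gene, reads$sample_id)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  cond <- reads |>
    dplyr::distinct(.data$sample_id, .data$condition)
  conditions <- stats::setNames(cond$condition, cond$sample_id)[colnames(counts)]
  list(counts = counts, conditions = conditions)
}

#' Median-of-ratios size factors
#'
#' DESeq-style: per sample, the median over genes (with all-positive counts)
#' of the ratio of the count to the gene's geometric mean across samples.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene with positive counts in all samples; use a pseudo-reference")
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(stats::median(col - loggeo)))
  stats::setNames(sf, colnames(counts))
}

#' Negative-binomial Wald test for differential expression
#'
#' Per gene: normalized condition means, pooled moment dispersion
#' `alpha = max(alpha_floor, (s^2 - mu_bar)/mu_bar^2)` from within-condition
#' residuals, `log2_fc = log2((mu_stim + 0.5)/(mu_ctrl + 0.5))`, a
#' delta-method standard error from the NB variance `mu + alpha mu^2`, a
#' two-sided normal p-value on `z = log2_fc / se`, and BH adjustment across
#' tested genes. All-zero genes are excluded (and recorded in the
#' `"n_excluded"` attribute).
#'
#' @param counts Integer matrix, genes x samples.
#' @param conditions Named character vector sample -> condition.
#' @param sf Size factors; computed with [size_factors()] if missing.
#' @param alpha_floor Dispersion floor.
#' @param alpha Significance level on the adjusted p-value.
#' @return Tibble: `gene_id`, `base_mean`, `log2_fc`, `se`, `wald_z`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
nb_wald_test <- function(counts, conditions, sf = NULL, alpha_floor = 1e-8,
                         alpha = 0.05) {
  conditions <- conditions[colnames(counts)]
  if (anyNA(conditions)) stop("conditions must be named for every sample")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf[colnames(counts)], "/")
  keep <- rowSums(counts) > 0
  n_excluded <- sum(!keep)
  norm <- norm[keep, , drop = FALSE]
  ctrl <- conditions == "control"
  stim <- conditions == "stimulated"
  n_c <- sum(ctrl); n_s <- sum(stim)
  if (n_c < 1L || n_s < 1L) stop("need samples in both conditions")
  mu_c <- rowMeans(norm[, ctrl, drop = FALSE])
  mu_s <- rowMeans(norm[, stim, drop = FALSE])
  mu_bar <- rowMeans(norm)
  # pooled within-condition residual variance
  if (n_c >= 2L && n_s >= 2L) {
    ss <- rowSums((norm[, ctrl, drop = FALSE] - mu_c)^2) +
      rowSums((norm[, stim, drop = FALSE] - mu_s)^2)
    s2 <- ss / (n_c + n_s - 2)
    disp <- pmax(alpha_floor, (s2 - mu_bar) / mu_bar^2)
  } else {
    # too few replicates per gene: pool a single dispersion across genes
    ss <- rowSums((norm - mu_bar)^2) / max(1, ncol(norm) - 1)
    disp_g <- (ss - mu_bar) / mu_bar^2
    disp <- rep(pmax(alpha_floor, stats::median(disp_g, na.rm = TRUE)),
                nrow(norm))
  }
  log2_fc <- log2((mu_s + 0.5) / (mu_c + 0.5))
  var_c <- (mu_c + disp * mu_c^2) / n_c
  var_s <- (mu_s + disp * mu_s^2) / n_s
  se <- sqrt(var_s / (mu_s + 0.5)^2 + var_c / (mu_c + 0.5)^2) / log(2)
  se <- pmax(se, 1e-12)
  z <- log2_fc / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- tibble::tibble(
    gene_id = rownames(norm), base_mean = unname(mu_bar),
    log2_fc = unname(log2_fc), se = unname(se), wald_z = unname(z),
    p_raw = unname(p), p_adj = bh_adjust(unname(p)))
  out$significant <- out$p_adj < alpha
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Differential expression from a read table
#'
#' Convenience wrapper: QC filter, [count_matrix()], [size_factors()],
#' [nb_wald_test()].
#'
#' @param reads Per-read tibble.
#' @param transcripts Optional annotation (transcript -> gene mapping).
#' @param qc_allowed Accepted `qc_tag` values.
#' @param ... Passed to [nb_wald_test()].
#' @return Tibble of per-gene results.
#' @export
differential_expression <- function(reads, transcripts = NULL,
                                    qc_allowed = c("PASS", "SUFFCLIP"), ...) {
  reads <- filter_qc(reads, qc_allowed)
  cm <- count_matrix(reads, transcripts)
  nb_wald_test(cm$counts, cm$conditions, ...)
}
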