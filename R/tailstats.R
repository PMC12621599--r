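# Per-transcript differential adenylation and tail-composition summaries.

#' Configuration for differential adenylation
#'
#' @param min_reads Minimum reads per transcript in *each* condition (>= 2).
#' @param alpha Significance level on the BH-adjusted p-value.
#' @param delta_threshold Minimum absolute median tail-length difference, nt
#'   (strict `>`).
#' @param effect_bins Cohen's d boundaries for negligible/small/medium/large.
#' @param qc_allowed Accepted `qc_tag` values.
#' @return A list of class `tail_test_config`.
#' @export
tail_test_config <- function(min_reads = 10L, alpha = 0.05, delta_threshold = 5,
                             effect_bins = c(0.2, 0.5, 0.8),
                             qc_allowed = c("PASS", "SUFFCLIP")) {
  stopifnot(min_reads >= 2L, alpha > 0, alpha < 1,
            length(effect_bins) == 3L, all(diff(effect_bins) > 0))
  structure(list(min_reads = as.integer(min_reads), alpha = alpha,
                 delta_threshold = delta_threshold, effect_bins = effect_bins,
                 qc_allowed = qc_allowed),
            class = "tail_test_config")
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The rank-sum statistic for `x` (`U`) with an exact two-sided p-value when
#' the smaller group has at most `exact_max` observations and there are no
#' ties, and the normal approximation with tie and continuity corrections
#' otherwise.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Largest min-group size for the exact path.
#' @return List with `U` and `p` (two-sided, in (0, 1]).
#' @export
ranksum_test <- function(x, y, exact_max = 8L) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && min(nx, ny) <= exact_max) {
    if (U > nx * ny / 2) {
      p <- 2 * (1 - stats::pwilcox(U - 1, nx, ny))
    } else {
      p <- 2 * stats::pwilcox(U, nx, ny)
    }
    p <- min(1, p)
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- (nx * ny / 12) * ((nx + ny + 1) -
      sum(tie_tab^3 - tie_tab) / ((nx + ny) * (nx + ny - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' `d = (mean(y) - mean(x)) / s_pooled` with the unbiased pooled sample SD.
#' A zero pooled SD yields `d = 0` with attribute `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return Numeric scalar.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(structure(0, degenerate = TRUE))
  (mean(y) - mean(x)) / sqrt(sp2)
}

#' Bin an effect size
#'
#' Uses `|d|`; boundaries are inclusive on the lower side: `|d| < 0.2`
#' negligible, `0.2 <= |d| < 0.5` small, `0.5 <= |d| < 0.8` medium,
#' `|d| >= 0.8` large.
#'
#' @param d Cohen's d (vectorized).
#' @param bins Increasing boundaries.
#' @return Character vector of classes.
#' @export
classify_effect_size <- function(d, bins = c(0.2, 0.5, 0.8)) {
  a <- abs(d)
  dplyr::case_when(
    a < bins[1] ~ "negligible",
    a < bins[2] ~ "small",
    a < bins[3] ~ "medium",
    TRUE ~ "large")
}

#' Per-transcript differential adenylation
#'
#' Filters reads to the allowed QC tags, tests every transcript with at least
#' `min_reads` reads in *both* conditions with the two-sample rank-sum test,
#' adjusts with Benjamini-Hochberg across the tested transcripts only, and
#' flags transcripts as significant under the dual rule: adjusted p below
#' `alpha` *and* `|delta_median| > delta_threshold` nt. Both the median and
#' the mean tail-length differences (stimulated - control) are reported.
#'
#' @param reads Per-read tibble (tail-table schema).
#' @param config A [tail_test_config()].
#' @return Tibble with one row per tested transcript: sample sizes, medians,
#'   means, deltas, `U`, `p_raw`, `p_adj`, `cohens_d`, `effect_class`,
#'   `significant`.
#' @export
differential_adenylation <- function(reads, config = tail_test_config()) {
  reads <- filter_qc(reads, config$qc_allowed)
  counts <- reads |>
    dplyr::count(.data$transcript_id, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n", values_fill = 0L)
  if (!"control" %in% names(counts)) counts$control <- 0L
  if (!"stimulated" %in% names(counts)) counts$stimulated <- 0L
  testable <- counts$transcript_id[counts$control >= config$min_reads &
                                     counts$stimulated >= config$min_reads]
  if (length(testable) == 0L) {
    warning("no transcript passes the per-condition read threshold")
    return(tibble::tibble(
      transcript_id = character(), n_control = integer(), n_stimulated = integer(),
      median_control = double(), median_stimulated = double(),
      mean_control = double(), mean_stimulated = double(),
      delta_median = double(), delta_mean = double(), U = double(),
      p_raw = double(), p_adj = double(), cohens_d = double(),
      effect_class = character(), significant = logical()))
  }
  res <- reads |>
    dplyr::filter(.data$transcript_id %in% testable) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(res = {
      x <- .data$tail_length[.data$condition == "control"]
      y <- .data$tail_length[.data$condition == "stimulated"]
      rs <- ranksum_test(x, y)
      d <- cohens_d(x, y)
      list(tibble::tibble(
        n_control = length(x), n_stimulated = length(y),
        median_control = stats::median(x), median_stimulated = stats::median(y),
        mean_control = mean(x), mean_stimulated = mean(y),
        delta_median = stats::median(y) - stats::median(x),
        delta_mean = mean(y) - mean(x),
        U = rs$U, p_raw = rs$p, cohens_d = as.numeric(d)))
    }, .groups = "drop") |>
    tidyr::unnest("res")
  res$p_adj <- bh_adjust(res$p_raw)
  res$effect_class <- classify_effect_size(res$cohens_d, config$effect_bins)
  res$significant <- res$p_adj < config$alpha &
    abs(res$delta_median) > config$delta_threshold
  dplyr::relocate(res, "p_adj", .after = "p_raw")
}

#' Poly(A) tail composition summary
#'
#' A read is "decorated" when its tail sequence contains at least one
#' non-adenosine. Reads lacking a tail sequence are excluded and counted in
#' the `n_no_seq` audit field.
#'
#' @param reads Per-read tibble.
#' @param group_by Optional column to summarise by (e.g. `"transcript_id"`);
#'   `NULL` gives a single global summary.
#' @param qc_allowed Accepted `qc_tag` values (`NULL` keeps all, including
#'   FAIL, for auditing).
#' @param length_bin Tail-length bin width (nt) for the decoration-rate
#'   profile.
#' @return Tibble with one row per group: `n_reads`, `n_no_seq`,
#'   `n_decorated`, `frac_decorated`, per-base non-A counts (`n_G`, `n_C`,
#'   `n_U`), and list-columns `nonA_histogram` (count of reads by
#'   non-adenosines per tail) and `rate_by_length` (decoration rate per
#'   tail-length bin).
#' @export
composition_summary <- function(reads, group_by = NULL,
                                qc_allowed = c("PASS", "SUFFCLIP"),
                                length_bin = 20L) {
  if (!is.null(qc_allowed)) reads <- filter_qc(reads, qc_allowed)
  n_no_seq_all <- sum(!nzchar(reads$tail_seq))
  with_seq <- reads[nzchar(reads$tail_seq), , drop = FALSE]
  count_base <- function(s, base) nchar(s) - nchar(gsub(base, "", s, fixed = TRUE))
  with_seq$n_nonA <- nchar(gsub("A", "", with_seq$tail_seq, fixed = TRUE))
  with_seq$n_G <- count_base(with_seq$tail_seq, "G")
  with_seq$n_C <- count_base(with_seq$tail_seq, "C")
  with_seq$n_U <- count_base(with_seq$tail_seq, "T")
  key <- if (is.null(group_by)) rep("global", nrow(with_seq)) else with_seq[[group_by]]
  with_seq$.scope <- key
  no_seq_by <- if (is.null(group_by)) {
    tibble::tibble(.scope = "global", n_no_seq = n_no_seq_all)
  } else {
    reads |>
      dplyr::filter(!nzchar(.data$tail_seq)) |>
      dplyr::count(.scope = .data[[group_by]], name = "n_no_seq")
  }
  out <- with_seq |>
    dplyr::group_by(.data$.scope) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      n_decorated = sum(.data$n_nonA > 0L),
      frac_decorated = mean(.data$n_nonA > 0L),
      n_G = sum(.data$n_G), n_C = sum(.data$n_C), n_U = sum(.data$n_U),
      nonA_histogram = list({
        nn <- .data$n_nonA
        tab <- table(nn)
        tibble::tibble(n_nonA = as.integer(names(tab)),
                       n_reads = as.integer(tab))
      }),
      rate_by_length = list({
        bin_lo <- (.data$tail_length %/% length_bin) * length_bin
        dec <- .data$n_nonA > 0L
        agg <- tapply(dec, bin_lo, mean)
        cnt <- tapply(dec, bin_lo, length)
        tibble::tibble(bin_lo = as.integer(names(agg)),
                       n_reads = as.integer(cnt),
                       frac_decorated = as.numeric(agg))
      }),
      .groups = "drop") |>
    dplyr::left_join(no_seq_by, by = ".scope") |>
    dplyr::mutate(n_no_seq = dplyr::coalesce(.data$n_no_seq, 0L)) |>
    dplyr::rename(scope = ".scope") |>
    dplyr::relocate("n_no_seq", .after = "n_reads")
  out
}
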