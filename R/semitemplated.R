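# Semi-templated tail discovery: A/T-rich terminal-window rules applied to
# annotation-derived and PAS-derived 3' ends, merged, then filtered by read
# and decoration support.

#' Semi-templated calling configuration
#'
#' @param window Terminal window, nt.
#' @param at_fraction_threshold Rule 1: window A/T fraction must *exceed*
#'   this (strict `>`).
#' @param run_length Rule 2: minimum A/T run length (inclusive `>=`).
#' @param terminal_run Number of terminal nt that must all be A/T for rule 2.
#' @param min_reads Minimum QC-passing reads per transcript.
#' @param min_decorated Minimum reads with a non-adenosine in the tail.
#' @return A list of class `semitemplated_config`.
#' @export
semitemplated_config <- function(window = 60L, at_fraction_threshold = 0.60,
                                 run_length = 13L, terminal_run = 3L,
                                 min_reads = 10L, min_decorated = 3L) {
  stopifnot(terminal_run <= run_length, run_length <= window,
            at_fraction_threshold > 0, at_fraction_threshold < 1,
            min_reads >= 1L, min_decorated >= 0L)
  structure(list(window = as.integer(window),
                 at_fraction_threshold = at_fraction_threshold,
                 run_length = as.integer(run_length),
                 terminal_run = as.integer(terminal_run),
                 min_reads = as.integer(min_reads),
                 min_decorated = as.integer(min_decorated)),
            class = "semitemplated_config")
}

#' A/T fraction of a sequence
#'
#' @param seq Non-empty DNA string(s).
#' @return `(#A + #T) / length`, vectorized.
#' @export
at_fraction <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence")
  at <- nchar(seq) - nchar(gsub("[AT]", "", seq))
  at / nchar(seq)
}

#' Longest A/T run and terminal A/T check
#'
#' @param seq Non-empty DNA string.
#' @param terminal_run Number of terminal characters that must all be A/T.
#' @return List with `run_length` (longest run of A/T characters) and
#'   `terminal_ok` (all of the last `terminal_run` characters are A/T).
#' @export
max_at_run <- function(seq, terminal_run = 3L) {
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "")[[1]]
  at <- chars %in% c("A", "T")
  run <- if (any(at)) { r <- rle(at); max(r$lengths[r$values]) } else 0L
  n <- length(chars)
  tok <- n >= terminal_run && all(at[(n - terminal_run + 1L):n])
  list(run_length = as.integer(run), terminal_ok = tok)
}

#' Candidate terminal windows (annotation- and PAS-derived)
#'
#' One window per annotated 3'UTR end (source `reference_utr`) plus one per
#' called PAS anchor (the `window` nt of mRNA-sense sequence ending at the
#' anchor; source `pas_predicted`). Windows truncated at a contig or UTR
#' boundary are flagged. PAS clusters whose gene has no transcript in the
#' annotation are skipped and counted in the `"n_skipped_pas"` attribute.
#'
#' @param transcripts Annotation tibble.
#' @param genome A [Biostrings::DNAStringSet].
#' @param pas_clusters Optional tibble from [cluster_read_ends()].
#' @param config A [semitemplated_config()].
#' @return Tibble: `transcript_id`, `source`, `window_seq`, `truncated`.
#' @export
candidate_windows <- function(transcripts, genome, pas_clusters = NULL,
                              config = semitemplated_config()) {
  w <- config$window
  with_utr <- transcripts[!is.na(transcripts$utr3_start), , drop = FALSE]
  ref <- terminal_windows(with_utr, genome, w)
  ref <- tibble::tibble(transcript_id = ref$transcript_id, source = "reference_utr",
                        window_seq = ref$window_seq,
                        truncated = ref$window_len < w)
  n_skipped <- 0L
  pas <- NULL
  if (!is.null(pas_clusters) && nrow(pas_clusters) > 0L) {
    known <- pas_clusters$gene_id %in% transcripts$gene_id
    n_skipped <- sum(!known)
    cl <- pas_clusters[known, , drop = FALSE]
    if (nrow(cl) > 0L) {
      chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
      len <- unname(chrom_len[cl$chrom])
      plus <- cl$strand == "+"
      s <- ifelse(plus, pmax(0L, cl$anchor + 1L - w), cl$anchor)
      e <- ifelse(plus, cl$anchor + 1L, pmin(len, cl$anchor + w))
      seq <- unname(substr(as.character(genome[cl$chrom]), s + 1L, e))
      if (any(!plus)) {
        seq[!plus] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seq[!plus])))
      }
      tx_by_gene <- split(transcripts$transcript_id, transcripts$gene_id)
      tids <- tx_by_gene[cl$gene_id]
      reps <- lengths(tids)
      pas <- tibble::tibble(
        transcript_id = unlist(tids, use.names = FALSE),
        source = "pas_predicted",
        window_seq = rep(seq, reps),
        truncated = rep(nchar(seq) < w, reps))
    }
  }
  out <- dplyr::bind_rows(ref, pas)
  attr(out, "n_skipped_pas") <- n_skipped
  out
}

#' Call semi-templated tail candidates
#'
#' Per window: rule 1 is a window A/T fraction strictly above the threshold;
#' rule 2 is an A/T run of at least `run_length` anywhere in the window with
#' the window's last `terminal_run` nt all A/T. Windows are reduced to
#' transcripts (rule passes OR-ed over a transcript's windows; source
#' `both` when reference- and PAS-derived windows were present). Candidates
#' are then filtered on read support: at least `min_reads` QC-passing reads
#' and at least `min_decorated` tails containing a non-adenosine. The
#' bookkeeping counts of every intermediate set are in the `"set_sizes"`
#' attribute (rule1, rule2, per-source and merged candidate counts, and the
#' final called count).
#'
#' @param windows Tibble from [candidate_windows()].
#' @param reads Per-read tibble.
#' @param config A [semitemplated_config()].
#' @param qc_allowed Accepted `qc_tag` values.
#' @return Tibble with per-transcript rule fields, support counts and
#'   `called`.
#' @export
call_semitemplated <- function(windows, reads, config = semitemplated_config(),
                               qc_allowed = c("PASS", "SUFFCLIP")) {
  per_window <- windows |>
    dplyr::mutate(
      at_fraction = at_fraction(.data$window_seq),
      run = purrr::map(.data$window_seq, max_at_run, terminal_run = config$terminal_run),
      max_at_run = purrr::map_int(.data$run, "run_length"),
      terminal_ok = purrr::map_lgl(.data$run, "terminal_ok"),
      rule1 = .data$at_fraction > config$at_fraction_threshold,
      rule2 = .data$max_at_run >= config$run_length & .data$terminal_ok) |>
    dplyr::select(-"run")
  per_tx <- per_window |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      source = {
        src <- unique(.data$source[.data$rule1 | .data$rule2])
        if (length(src) == 0L) NA_character_
        else if (length(src) == 2L) "both"
        else src
      },
      at_fraction = max(.data$at_fraction),
      max_at_run = max(.data$max_at_run),
      terminal_ok = any(.data$terminal_ok),
      rule1 = any(.data$rule1), rule2 = any(.data$rule2),
      .groups = "drop")
  rule1_n <- sum(per_tx$rule1)
  rule2_n <- sum(per_tx$rule2)
  ref_n <- per_window |>
    dplyr::filter(.data$source == "reference_utr", .data$rule1 | .data$rule2) |>
    dplyr::distinct(.data$transcript_id) |> nrow()
  pas_n <- per_window |>
    dplyr::filter(.data$source == "pas_predicted", .data$rule1 | .data$rule2) |>
    dplyr::distinct(.data$transcript_id) |> nrow()
  candidates <- per_tx[per_tx$rule1 | per_tx$rule2, , drop = FALSE]

  reads <- filter_qc(reads, qc_allowed)
  support <- reads |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      n_decorated = sum(nzchar(.data$tail_seq) &
                          grepl("[^A]", .data$tail_seq)),
      .groups = "drop")
  out <- candidates |>
    dplyr::left_join(support, by = "transcript_id") |>
    dplyr::mutate(
      n_reads = dplyr::coalesce(.data$n_reads, 0L),
      n_decorated = dplyr::coalesce(.data$n_decorated, 0L),
      called = (.data$rule1 | .data$rule2) &
        .data$n_reads >= config$min_reads &
        .data$n_decorated >= config$min_decorated)
  attr(out, "set_sizes") <- c(
    rule1 = rule1_n, rule2 = rule2_n,
    reference_utr = ref_n, pas_predicted = pas_n,
    merged = nrow(candidates), called = sum(out$called))
  out
}
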