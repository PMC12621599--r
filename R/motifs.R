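# FIMO-style PWM scanning of 3'UTRs for cytoplasmic polyadenylation
# elements: MEME-minimal motif input, log-odds scoring against a 0-order
# background, and exact p-values via dynamic programming over
# integer-scaled scores.

DNA_BASES <- c("A", "C", "G", "T")

#' Read MEME minimal motif text
#'
#' Parses the MEME minimal format (`MEME version`, optional
#' `Background letter frequencies`, `MOTIF <id>` blocks with
#' `letter-probability matrix` sections over the ACGT alphabet).
#'
#' @param path Path to a MEME minimal file.
#' @return List of motifs; each a list with `motif_id`, `width` and `probs`
#'   (a width x 4 matrix, columns A/C/G/T, rows summing to 1).
#' @export
read_meme_motifs <- function(path) {
  lines <- trimws(readLines(path))
  if (!any(grepl("^MEME version", lines))) stop("not a MEME minimal file (missing 'MEME version' header)")
  motif_starts <- grep("^MOTIF ", lines)
  if (length(motif_starts) == 0L) stop("no MOTIF blocks found")
  bg <- NULL
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1L && bg_at < motif_starts[1]) {
    toks <- strsplit(lines[bg_at + 1L], "\\s+")[[1]]
    vals <- as.numeric(toks[c(FALSE, TRUE)])
    names(vals) <- toks[c(TRUE, FALSE)]
    bg <- vals[DNA_BASES]
  }
  motifs <- lapply(seq_along(motif_starts), function(k) {
    from <- motif_starts[k]
    to <- if (k < length(motif_starts)) motif_starts[k + 1L] - 1L else length(lines)
    block <- lines[from:to]
    motif_id <- strsplit(block[1], "\\s+")[[1]][2]
    if (is.na(motif_id) || !nzchar(motif_id)) stop("MOTIF line without identifier")
    lp <- grep("^letter-probability matrix", block)
    if (length(lp) != 1L) stop("motif ", motif_id, ": missing letter-probability matrix header")
    w <- suppressWarnings(as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", block[lp])))
    rows <- block[(lp + 1L):length(block)]
    rows <- rows[nzchar(rows)]
    rows <- rows[grepl("^[0-9.eE+ -]+$", rows)]
    if (is.na(w)) w <- length(rows)
    if (length(rows) < w) stop("motif ", motif_id, ": fewer matrix rows than w")
    probs <- do.call(rbind, lapply(rows[seq_len(w)], function(r) {
      as.numeric(strsplit(r, "\\s+")[[1]])
    }))
    if (ncol(probs) != 4L) stop("motif ", motif_id, ": matrix must have 4 columns (ACGT)")
    colnames(probs) <- DNA_BASES
    bad <- abs(rowSums(probs) - 1) > 1e-6
    if (any(bad)) stop("motif ", motif_id, ": position ", which(bad)[1],
                       " probabilities do not sum to 1")
    list(motif_id = motif_id, width = w, probs = probs)
  })
  attr(motifs, "background") <- bg
  motifs
}

#' Write motifs in MEME minimal format
#'
#' @param motifs List of motifs (as from [read_meme_motifs()]).
#' @param path Output path.
#' @param background Optional named background frequencies (A/C/G/T).
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, background = NULL) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  if (!is.null(background)) {
    lines <- c(lines, "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, background[DNA_BASES]),
                     collapse = " "), "")
  }
  for (m in motifs) {
    lines <- c(lines, paste("MOTIF", m$motif_id),
               sprintf("letter-probability matrix: alength= 4 w= %d", m$width),
               apply(m$probs, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a log-odds matrix from letter probabilities
#'
#' `s[i, b] = log2(((p[i, b] + c * q_b) / (1 + c)) / q_b)` with pseudocount
#' `c` and background `q`.
#'
#' @param motif Motif list (`motif_id`, `width`, `probs`).
#' @param background Named positive frequencies over A/C/G/T, summing to 1.
#' @param pseudocount Pseudocount `c`.
#' @return List with `motif_id`, `width`, `scores` (width x 4), `background`.
#' @export
build_log_odds <- function(motif, background, pseudocount = 0.01) {
  background <- background[DNA_BASES]
  if (any(is.na(background)) || any(background <= 0)) {
    stop("background must be positive over A, C, G, T")
  }
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  q <- matrix(background, nrow = motif$width, ncol = 4L, byrow = TRUE)
  s <- log2(((motif$probs + pseudocount * q) / (1 + pseudocount)) / q)
  colnames(s) <- DNA_BASES
  list(motif_id = motif$motif_id, width = motif$width, scores = s,
       background = background)
}

#' Exact null distribution of integer-scaled motif scores
#'
#' Per-position scores are scaled by `scale` and rounded to integers; the
#' null distribution of the total integer score under the 0-order background
#' model is built by positional convolution. Supports exact
#' `P(score >= t)` lookups.
#'
#' @param lom Log-odds matrix from [build_log_odds()].
#' @param scale Integer scaling factor.
#' @return List of class `score_null`: `int_scores` (width x 4 integer
#'   matrix), `support` (integer scores), `prob`, `pval` (upper-tail
#'   probabilities aligned with `support`), `scale`.
#' @export
score_distribution <- function(lom, scale = 1000L) {
  int_scores <- round(lom$scores * scale)
  storage.mode(int_scores) <- "integer"
  bg <- lom$background
  offset <- -sum(apply(int_scores, 1, min))  # shift to nonnegative indices
  probs <- 1
  base_min <- 0L
  for (i in seq_len(lom$width)) {
    row <- int_scores[i, ]
    rmin <- min(row)
    span <- max(row) - rmin
    new <- numeric(length(probs) + span)
    for (b in seq_len(4L)) {
      k <- row[b] - rmin
      new[(1L + k):(length(probs) + k)] <-
        new[(1L + k):(length(probs) + k)] + probs * bg[b]
    }
    probs <- new
    base_min <- base_min + rmin
  }
  support <- base_min + seq_along(probs) - 1L
  keep <- probs > 0
  support <- support[keep]
  probs <- probs[keep]
  pval <- rev(cumsum(rev(probs)))
  structure(list(int_scores = int_scores, support = support, prob = probs,
                 pval = pval, scale = scale),
            class = "score_null")
}

# P(score >= t) for integer scores t (vectorized)
score_pvalue <- function(null, t) {
  idx <- findInterval(t - 1L, null$support) + 1L
  out <- ifelse(idx > length(null$support), 0, null$pval[pmax(idx, 1L)])
  ifelse(t <= null$support[1], 1, out)
}

#' Scan sequences for motif hits
#'
#' Every position whose exact p-value (from [score_distribution()]) is at
#' most `threshold` is reported. Sequences shorter than the motif yield no
#' hits. Sense strand only.
#'
#' @param sequences Named character vector (DNA, uppercase).
#' @param lom Log-odds matrix from [build_log_odds()].
#' @param threshold p-value threshold (FIMO-style, default 1e-4).
#' @param null Optional precomputed [score_distribution()].
#' @return Tibble: `motif_id`, `sequence_id`, `start` (0-based), `matched`,
#'   `score`, `p_value`.
#' @export
scan_motif <- function(sequences, lom, threshold = 1e-4, null = NULL) {
  if (is.null(null)) null <- score_distribution(lom)
  w <- lom$width
  empty <- tibble::tibble(motif_id = character(), sequence_id = character(),
                          start = integer(), matched = character(),
                          score = double(), p_value = double())
  if (is.null(names(sequences))) names(sequences) <- as.character(seq_along(sequences))
  out <- purrr::imap(sequences, function(s, id) {
    L <- nchar(s)
    if (L < w) return(NULL)
    codes <- match(strsplit(s, "")[[1]], DNA_BASES)
    n_pos <- L - w + 1L
    int_tot <- integer(n_pos)
    real_tot <- numeric(n_pos)
    ok <- rep(TRUE, n_pos)
    for (i in seq_len(w)) {
      b <- codes[i:(i + n_pos - 1L)]
      ok <- ok & !is.na(b)
      bi <- ifelse(is.na(b), 1L, b)
      int_tot <- int_tot + null$int_scores[cbind(i, bi)]
      real_tot <- real_tot + lom$scores[cbind(i, bi)]
    }
    p <- score_pvalue(null, int_tot)
    hit <- ok & p <= threshold
    if (!any(hit)) return(NULL)
    starts <- which(hit)
    tibble::tibble(motif_id = lom$motif_id, sequence_id = id,
                   start = starts - 1L,
                   matched = substring(s, starts, starts + w - 1L),
                   score = real_tot[hit], p_value = p[hit])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) empty else res
}

#' Estimate a 0-order background from sequences
#'
#' @param sequences Character vector of DNA sequences.
#' @return Named frequencies over A/C/G/T (pseudocount 1 per base).
#' @export
background_from_sequences <- function(sequences) {
  all <- paste(sequences, collapse = "")
  counts <- vapply(DNA_BASES, function(b) {
    nchar(all) - nchar(gsub(b, "", all, fixed = TRUE))
  }, numeric(1)) + 1
  counts / sum(counts)
}

#' Annotate transcripts with CPE motif presence
#'
#' Scans the full 3'UTR sense sequence of every transcript for each motif
#' and flags presence per motif (`has_<motif_id>`). Transcripts without an
#' annotated 3'UTR get `FALSE` flags and are counted in the `"n_no_utr"`
#' attribute. The background defaults to the 0-order model of the scanned
#' UTR set.
#'
#' @param transcripts Annotation tibble.
#' @param genome A [Biostrings::DNAStringSet].
#' @param motifs Motif list (from [read_meme_motifs()]).
#' @param threshold p-value threshold.
#' @param background Optional named background; estimated from the UTR
#'   sequences when `NULL`.
#' @param pseudocount Log-odds pseudocount.
#' @return Tibble: `transcript_id` plus one logical flag column per motif.
#' @export
annotate_cpe <- function(transcripts, genome, motifs, threshold = 1e-4,
                         background = NULL, pseudocount = 0.01) {
  has_utr <- !is.na(transcripts$utr3_start)
  with_utr <- transcripts[has_utr, , drop = FALSE]
  utr_seqs <- stats::setNames(
    purrr::pmap_chr(
      list(with_utr$chrom, with_utr$utr3_start, with_utr$utr3_end, with_utr$strand),
      function(chrom, s, e, strand) extract_sense(genome, chrom, s, e, strand)),
    with_utr$transcript_id)
  if (is.null(background)) background <- background_from_sequences(utr_seqs)
  out <- tibble::tibble(transcript_id = transcripts$transcript_id)
  for (m in motifs) {
    lom <- build_log_odds(m, background, pseudocount)
    hits <- scan_motif(utr_seqs, lom, threshold)
    flag <- transcripts$transcript_id %in% hits$sequence_id
    out[[paste0("has_", m$motif_id)]] <- flag & has_utr
  }
  attr(out, "n_no_utr") <- sum(!has_utr)
  out
}
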