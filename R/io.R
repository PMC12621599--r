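# Readers/writers and coordinate conventions.
#
# Internal convention: 0-based half-open intervals everywhere. GTF-lite
# (1-based closed) is converted at the parse/write boundary; BED is native
# 0-based half-open. `end_pos` of a read is the 0-based coordinate of its
# last templated nucleotide.

QC_LEVELS <- c("PASS", "SUFFCLIP", "FAIL")
CONDITION_LEVELS <- c("control", "stimulated")

#' Read a FASTA file into a named DNA sequence set
#'
#' Sequences are uppercased on load and any `U` is mapped to `T`; whether the
#' input used the RNA alphabet is recorded in the `"was_rna"` attribute.
#'
#' @param path Path to a FASTA file. Lines may wrap at any width.
#' @return A [Biostrings::DNAStringSet] with unique names and an attribute
#'   `was_rna` (logical).
#' @export
read_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no sequences in FASTA file: ", path)
  nm <- names(raw)
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  chars <- toupper(as.character(raw))
  if (any(nchar(chars) == 0L)) {
    stop("empty FASTA record: ", paste(nm[nchar(chars) == 0L], collapse = ", "))
  }
  was_rna <- any(grepl("U", chars, fixed = TRUE))
  chars <- gsub("U", "T", chars, fixed = TRUE)
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) stop("non-ACGTN characters in sequences: ",
                     paste(nm[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- nm
  attr(out, "was_rna") <- was_rna
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

parse_gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(paste0(key, ' "'), attrs)
  out[hit] <- sub(paste0('^.*', key, ' "([^"]*)".*$'), "\\1", attrs[hit])
  out
}

#' Read a GTF-lite transcript annotation
#'
#' Accepts tab-separated GTF-like lines with feature types `gene`,
#' `transcript`, `exon` and `three_prime_utr`, and `gene_id`/`transcript_id`
#' attributes. 1-based closed intervals are converted to the internal 0-based
#' half-open convention.
#'
#' @param path Path to a GTF-lite file.
#' @return A tibble with one row per transcript: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `tx_start`, `tx_end`, a list-column `exons` of
#'   two-column integer matrices (`start`, `end`; 0-based half-open, sorted),
#'   and `utr3_start`/`utr3_end` (`NA` when no 3'UTR is annotated).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) stop("malformed GTF-lite line (fewer than 9 fields) at line ",
                         which(nf < 9L)[1])
  tab <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    feature = vapply(fields, `[[`, "", 3L),
    start1 = as.integer(vapply(fields, `[[`, "", 4L)),
    end1 = as.integer(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 7L),
    attrs = vapply(fields, `[[`, "", 9L)
  )
  tab <- tab[tab$feature %in% c("transcript", "exon", "three_prime_utr"), , drop = FALSE]
  if (!all(tab$strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         paste(unique(setdiff(tab$strand, c("+", "-"))), collapse = ", "))
  }
  tab$gene_id <- parse_gtf_attr(tab$attrs, "gene_id")
  tab$transcript_id <- parse_gtf_attr(tab$attrs, "transcript_id")
  if (anyNA(tab$transcript_id)) stop("record without transcript_id attribute")
  # to 0-based half-open
  tab$start <- tab$start1 - 1L
  tab$end <- tab$end1
  tx_ids <- unique(tab$transcript_id[tab$feature == "transcript"])
  if (anyDuplicated(tab$transcript_id[tab$feature == "transcript"])) {
    stop("duplicate transcript_id in annotation")
  }
  rows <- lapply(tx_ids, function(tid) {
    sub <- tab[tab$transcript_id == tid, , drop = FALSE]
    txr <- sub[sub$feature == "transcript", , drop = FALSE]
    ex <- sub[sub$feature == "exon", , drop = FALSE]
    ut <- sub[sub$feature == "three_prime_utr", , drop = FALSE]
    if (nrow(ex) == 0L) stop("transcript without exons: ", tid)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in transcript: ", tid)
    }
    if (any(ex$start < txr$start) || any(ex$end > txr$end)) {
      stop("exon outside declared transcript span for transcript: ", tid)
    }
    u_start <- NA_integer_; u_end <- NA_integer_
    if (nrow(ut) > 1L) stop("multiple three_prime_utr records for transcript: ", tid)
    if (nrow(ut) == 1L) {
      u_start <- ut$start; u_end <- ut$end
      covered <- any(ex$start <= u_start & ex$end >= u_end)
      if (!covered) {
        # allow coverage by a union of adjacent exons
        pos <- u_start
        for (k in seq_len(nrow(ex))) {
          if (ex$start[k] <= pos && pos < ex$end[k]) pos <- ex$end[k]
        }
        covered <- pos >= u_end
      }
      if (!covered) stop("three_prime_utr not contained in exons of transcript: ", tid)
    }
    tibble::tibble(
      gene_id = txr$gene_id[1], transcript_id = tid,
      chrom = txr$chrom[1], strand = txr$strand[1],
      tx_start = txr$start[1], tx_end = txr$end[1],
      exons = list(cbind(start = ex$start, end = ex$end)),
      utr3_start = u_start, utr3_end = u_end
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a transcript annotation tibble as GTF-lite
#'
#' @param transcripts Tibble as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(transcripts, path) {
  lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    at <- sprintf('gene_id "%s"; transcript_id "%s";', tr$gene_id, tr$transcript_id)
    fmt <- function(feature, s, e) {
      sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\t%s",
              tr$chrom, feature, s + 1L, e, tr$strand, at)
    }
    lines <- c(lines, fmt("transcript", tr$tx_start, tr$tx_end))
    ex <- tr$exons[[1]]
    for (k in seq_len(nrow(ex))) lines <- c(lines, fmt("exon", ex[k, "start"], ex[k, "end"]))
    if (!is.na(tr$utr3_start)) {
      lines <- c(lines, fmt("three_prime_utr", tr$utr3_start, tr$utr3_end))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

TAIL_TABLE_COLS <- c("read_id", "transcript_id", "sample_id", "condition",
                     "tail_length", "tail_seq", "end_pos", "qc_tag")

#' Read a per-read poly(A) tail table
#'
#' A TSV with columns `read_id`, `transcript_id`, `sample_id`, `condition`,
#' `tail_length`, `tail_seq`, `end_pos`, `qc_tag`. `FAIL`-tagged reads are
#' retained (downstream analyses filter on `qc_tag`). Tail sequences given in
#' the RNA alphabet are normalized to DNA; the original alphabet is recorded
#' in the `"tail_alphabet"` attribute.
#'
#' @param path Path to the TSV.
#' @return A tibble of read records.
#' @export
read_tail_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    read_id = "c", transcript_id = "c", sample_id = "c", condition = "c",
    tail_length = "i", tail_seq = "c", end_pos = "i", qc_tag = "c"
  ), na = character(), progress = FALSE)
  if (!identical(names(tbl), TAIL_TABLE_COLS)) {
    stop("tail table must have columns: ", paste(TAIL_TABLE_COLS, collapse = ", "))
  }
  validate_read_records(tbl)
}

#' Validate (and normalize) a tibble of read records
#'
#' @param tbl Tibble with the tail-table columns.
#' @return The validated tibble (tail sequences normalized to DNA alphabet).
#' @export
validate_read_records <- function(tbl) {
  if (nrow(tbl) == 0L) {
    attr(tbl, "tail_alphabet") <- "DNA"
    return(tbl)
  }
  bad_cond <- !tbl$condition %in% CONDITION_LEVELS
  if (any(bad_cond)) stop("unknown condition value: ",
                          paste(unique(tbl$condition[bad_cond]), collapse = ", "))
  bad_qc <- !tbl$qc_tag %in% QC_LEVELS
  if (any(bad_qc)) stop("unknown qc_tag value: ",
                        paste(unique(tbl$qc_tag[bad_qc]), collapse = ", "))
  if (any(tbl$tail_length < 0L)) stop("negative tail_length")
  had_rna <- any(grepl("U", tbl$tail_seq, fixed = TRUE))
  tbl$tail_seq <- gsub("U", "T", toupper(tbl$tail_seq), fixed = TRUE)
  bad_alpha <- grepl("[^ACGT]", tbl$tail_seq)
  if (any(bad_alpha)) stop("tail_seq with non-ACGU/ACGT characters for read: ",
                           paste(utils::head(tbl$read_id[bad_alpha], 3), collapse = ", "))
  present <- nzchar(tbl$tail_seq)
  mism <- present & nchar(tbl$tail_seq) != tbl$tail_length
  if (any(mism)) {
    stop("tail_length does not match tail_seq length for read: ",
         paste(utils::head(tbl$read_id[mism], 3), collapse = ", "))
  }
  attr(tbl, "tail_alphabet") <- if (had_rna) "RNA" else "DNA"
  tbl
}

#' Write a per-read tail table as TSV
#'
#' @param reads Tibble of read records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tail_table <- function(reads, path) {
  readr::write_tsv(reads[, TAIL_TABLE_COLS], path, progress = FALSE)
  invisible(path)
}

#' Drop reads failing tail-length QC
#'
#' @param reads Tibble of read records.
#' @param qc_allowed Accepted `qc_tag` values.
#' @return Filtered tibble.
#' @export
filter_qc <- function(reads, qc_allowed = c("PASS", "SUFFCLIP")) {
  dplyr::filter(reads, .data$qc_tag %in% qc_allowed)
}

#' Read a BED6 file
#'
#' @param path Path to a BED6 file (0-based half-open, native).
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  tbl <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE)
  if (any(tbl$start >= tbl$end)) stop("BED record with start >= end")
  if (!all(tbl$strand %in% c("+", "-"))) stop("BED record with missing/unknown strand")
  tbl
}

#' Write PAS clusters (or any BED6-shaped tibble) as BED6
#'
#' For PAS clusters the interval is the cluster span, the name the cluster id
#' and the score the total read support.
#'
#' @param clusters Tibble of PAS clusters (from [cluster_read_ends()]) or a
#'   BED6-shaped tibble (`chrom`, `start`, `end`, `name`, `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(clusters, path) {
  if (all(c("pas_id", "span_start", "span_end") %in% names(clusters))) {
    bed <- tibble::tibble(chrom = clusters$chrom, start = clusters$span_start,
                          end = clusters$span_end, name = clusters$pas_id,
                          score = clusters$support_total, strand = clusters$strand)
  } else {
    bed <- clusters[, c("chrom", "start", "end", "name", "score", "strand")]
  }
  if (any(bed$start >= bed$end)) stop("BED record with start >= end")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Extract a genomic interval in mRNA sense
#'
#' Minus-strand intervals are reverse-complemented so the returned string
#' reads 5'->3' along the mRNA.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom Sequence name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar.
#' @export
extract_sense <- function(genome, chrom, start, end, strand) {
  if (!chrom %in% names(genome)) stop("unknown sequence: ", chrom)
  if (start < 0L || end > length(genome[[chrom]]) || start >= end) {
    stop("interval out of bounds for ", chrom, ": [", start, ",", end, ")")
  }
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Terminal 3'UTR windows in mRNA sense
#'
#' Returns, per transcript, the last `window` nt of the annotated 3'UTR with
#' the nucleotides adjacent to the poly(A) tail at the right end of the
#' string (antisense-strand transcripts are reverse-complemented). 3'UTRs
#' shorter than `window` yield the whole UTR.
#'
#' @param transcripts Annotation tibble (see [read_annotation()]).
#' @param genome A [Biostrings::DNAStringSet].
#' @param window Window size in nt (>= 1).
#' @return Tibble with `transcript_id`, `window_seq`, `window_len`.
#' @export
terminal_windows <- function(transcripts, genome, window = 60L) {
  stopifnot(window >= 1L)
  if (any(is.na(transcripts$utr3_start))) {
    stop("no annotated 3'UTR for transcript: ",
         paste(utils::head(transcripts$transcript_id[is.na(transcripts$utr3_start)], 3),
               collapse = ", "))
  }
  missing <- setdiff(transcripts$chrom, names(genome))
  if (length(missing) > 0L) stop("chromosome not in genome: ", missing[1])
  w <- pmin(window, transcripts$utr3_end - transcripts$utr3_start)
  plus <- transcripts$strand == "+"
  s <- ifelse(plus, transcripts$utr3_end - w, transcripts$utr3_start)
  e <- s + w
  seq <- unname(substr(as.character(genome[transcripts$chrom]), s + 1L, e))
  if (any(!plus)) {
    seq[!plus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq[!plus])))
  }
  tibble::tibble(transcript_id = transcripts$transcript_id,
                 window_seq = seq, window_len = as.integer(w))
}
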