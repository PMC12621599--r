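# Polyadenylation-site (PAS) calling from read 3' ends, genomic feature
# assignment, Fisher-exact differential usage, proximal/distal shift, and
# upstream polyadenylation-signal (hexamer) profiling.

# common single-substitution variants of the canonical signal
HEXAMER_VARIANTS <- c("AGTAAA", "TATAAA", "CATAAA", "GATAAA", "AATATA",
                      "AATACA", "AATAGA", "AATGAA", "ACTAAA", "TTTAAA")

#' APA configuration
#'
#' @param cluster_gap Single-linkage gap (nt) when clustering read ends.
#' @param min_support Minimum total reads per cluster.
#' @param fisher_alpha Nominal level of the per-PAS Fisher test.
#' @param adj_threshold BH-adjusted p-value threshold for a differential PAS.
#' @param hexamer_window Upstream window (nt) scanned for the signal hexamer.
#' @param include_variants Also count ten common single-substitution signal
#'   variants besides AATAAA/ATTAAA.
#' @return A list of class `apa_config`.
#' @export
apa_config <- function(cluster_gap = 24L, min_support = 3L, fisher_alpha = 0.05,
                       adj_threshold = 0.1, hexamer_window = 40L,
                       include_variants = FALSE) {
  stopifnot(cluster_gap >= 0L, min_support >= 1L,
            fisher_alpha > 0, fisher_alpha < 1,
            adj_threshold > 0, adj_threshold < 1, hexamer_window >= 6L)
  hexamer_set <- c("AATAAA", "ATTAAA")
  if (include_variants) hexamer_set <- c(hexamer_set, HEXAMER_VARIANTS)
  structure(list(cluster_gap = as.integer(cluster_gap),
                 min_support = as.integer(min_support),
                 fisher_alpha = fisher_alpha, adj_threshold = adj_threshold,
                 hexamer_window = as.integer(hexamer_window),
                 hexamer_set = hexamer_set),
            class = "apa_config")
}

#' Cluster read 3' ends into PAS calls
#'
#' Per gene and strand, single-linkage clustering of `end_pos` with maximum
#' gap `cluster_gap`; clusters with fewer than `min_support` reads are
#' dropped. The anchor is the modal end position (ties broken towards the
#' 3'-most position in mRNA orientation). The result is independent of read
#' input order.
#'
#' @param reads Per-read tibble (QC-filtered by the caller if desired).
#' @param transcripts Annotation tibble (gene/strand/chrom lookup).
#' @param config An [apa_config()].
#' @param qc_allowed Accepted `qc_tag` values.
#' @return Tibble of PAS clusters: `pas_id`, `gene_id`, `chrom`, `strand`,
#'   `anchor`, `span_start`, `span_end`, per-condition and total support,
#'   plus a `support_by_sample` list-column.
#' @export
cluster_read_ends <- function(reads, transcripts, config = apa_config(),
                              qc_allowed = c("PASS", "SUFFCLIP")) {
  if (!is.null(qc_allowed)) reads <- filter_qc(reads, qc_allowed)
  empty <- tibble::tibble(
    pas_id = character(), gene_id = character(), chrom = character(),
    strand = character(), anchor = integer(), span_start = integer(),
    span_end = integer(), support_total = integer(),
    support_control = integer(), support_stimulated = integer(),
    support_by_sample = list())
  if (nrow(reads) == 0L) return(empty)
  ann <- transcripts[, c("transcript_id", "gene_id", "chrom", "strand")]
  reads <- dplyr::inner_join(reads, ann, by = "transcript_id")
  out <- reads |>
    dplyr::arrange(.data$gene_id, .data$end_pos, .data$sample_id, .data$read_id) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(cluster = cumsum(c(0L, diff(.data$end_pos) > config$cluster_gap))) |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand, .data$cluster) |>
    dplyr::summarise(
      anchor = {
        tab <- table(.data$end_pos)
        modal <- as.integer(names(tab)[tab == max(tab)])
        if (.data$strand[1] == "+") max(modal) else min(modal)
      },
      span_start = min(.data$end_pos), span_end = max(.data$end_pos) + 1L,
      support_total = dplyr::n(),
      support_control = sum(.data$condition == "control"),
      support_stimulated = sum(.data$condition == "stimulated"),
      support_by_sample = list({
        key <- paste(.data$sample_id, .data$condition, sep = "\r")
        tab <- table(key)
        parts <- strsplit(names(tab), "\r", fixed = TRUE)
        tibble::new_tibble(list(
          sample_id = vapply(parts, `[[`, "", 1L),
          condition = vapply(parts, `[[`, "", 2L),
          n = as.integer(tab)), nrow = length(tab))
      }),
      .groups = "drop") |>
    dplyr::select(-"cluster")
  out <- out[out$support_total >= config$min_support, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out <- dplyr::arrange(out, .data$gene_id, .data$anchor)
  out <- out |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(pas_id = paste0(.data$gene_id, ":PAS", dplyr::row_number())) |>
    dplyr::ungroup()
  dplyr::relocate(out, "pas_id")
}

#' Assign PAS clusters to genomic features
#'
#' Precedence: `three_prime_utr` > `exon` > `intron` > `within_transcript` >
#' `unassigned`, judged by anchor overlap with the gene's transcripts. An
#' anchor inside a transcript span but in no exon is intronic;
#' `within_transcript` is the fallback when the span matches but the
#' transcript has no annotated 3'UTR to arbitrate.
#'
#' @param clusters Tibble from [cluster_read_ends()].
#' @param transcripts Annotation tibble.
#' @return `clusters` with a `feature` column.
#' @export
assign_pas_features <- function(clusters, transcripts) {
  feat <- vapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    txs <- transcripts[transcripts$gene_id == cl$gene_id &
                         transcripts$chrom == cl$chrom, , drop = FALSE]
    if (nrow(txs) == 0L) return("unassigned")
    a <- cl$anchor
    in_utr <- any(!is.na(txs$utr3_start) & txs$utr3_start <= a & a < txs$utr3_end)
    if (in_utr) return("three_prime_utr")
    in_exon <- any(vapply(txs$exons, function(ex) {
      any(ex[, "start"] <= a & a < ex[, "end"])
    }, logical(1)))
    if (in_exon) return("exon")
    in_span <- txs$tx_start <= a & a < txs$tx_end
    if (any(in_span)) {
      if (any(!is.na(txs$utr3_start[in_span]))) return("intron")
      return("within_transcript")
    }
    "unassigned"
  }, character(1))
  clusters$feature <- feat
  clusters
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sum of hypergeometric probabilities of all tables with the observed
#' margins whose point probability does not exceed the observed one (within
#' the conventional 1 + 1e-7 tolerance). A zero margin yields p = 1 with
#' attribute `degenerate = TRUE`.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(1, degenerate = TRUE))
  }
  stats::fisher.test(tab)$p.value
}

#' Differential PAS usage
#'
#' For every PAS of a gene with at least two called PASs: Fisher's exact
#' test of `[[pas_ctrl, others_ctrl], [pas_stim, others_stim]]`, BH across
#' all tested PASs, `differential` at `adj_threshold`. PASs are ranked
#' proximal/middle/distal in mRNA orientation (proximal = 5'-most).
#'
#' @param clusters Tibble from [cluster_read_ends()].
#' @param config An [apa_config()].
#' @param sf Optional named size factors for the normalized `log2_shift`
#'   (raw support is used when absent).
#' @return Tibble: `pas_id`, `gene_id`, table cells, `p_raw`, `p_adj`,
#'   `differential`, `rank`, `log2_shift`.
#' @export
differential_pas_usage <- function(clusters, config = apa_config(), sf = NULL) {
  multi <- clusters |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::ungroup()
  if (nrow(multi) == 0L) {
    message("no gene with >= 2 PAS clusters; nothing to test")
    return(tibble::tibble(pas_id = character(), gene_id = character(),
                          pas_control = integer(), others_control = integer(),
                          pas_stimulated = integer(), others_stimulated = integer(),
                          p_raw = double(), p_adj = double(),
                          differential = logical(), rank = character(),
                          log2_shift = double()))
  }
  norm_support <- function(row, cond) {
    bys <- row$support_by_sample[[1]]
    bys <- bys[bys$condition == cond, , drop = FALSE]
    if (is.null(sf)) sum(bys$n) else sum(bys$n / sf[bys$sample_id])
  }
  res <- multi |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(function(df, key) {
      ord <- order(df$anchor)
      if (df$strand[1] == "-") ord <- rev(ord)
      rank <- rep("middle", nrow(df))
      rank[ord[1]] <- "proximal"
      rank[ord[length(ord)]] <- "distal"
      tot_c <- sum(df$support_control); tot_s <- sum(df$support_stimulated)
      purrr::map_dfr(seq_len(nrow(df)), function(i) {
        a <- df$support_control[i]; b <- tot_c - a
        cc <- df$support_stimulated[i]; d <- tot_s - cc
        ns <- norm_support(df[i, ], "stimulated")
        nc <- norm_support(df[i, ], "control")
        tibble::tibble(
          pas_id = df$pas_id[i], gene_id = key$gene_id,
          pas_control = a, others_control = b,
          pas_stimulated = cc, others_stimulated = d,
          p_raw = as.numeric(fisher_exact(matrix(c(a, cc, b, d), 2L))),
          rank = rank[i],
          log2_shift = log2((ns + 0.5) / (nc + 0.5)))
      })
    }) |>
    dplyr::bind_rows()
  res$p_adj <- bh_adjust(res$p_raw)
  res$differential <- res$p_adj <= config$adj_threshold
  dplyr::relocate(res, "p_adj", .after = "p_raw")
}

#' Per-gene proximal and distal PAS expression shift
#'
#' `log2((normalized stimulated support + 0.5) / (normalized control support
#' + 0.5))` for the 5'-most (proximal) and 3'-most (distal) PAS of every
#' gene with at least two called PASs.
#'
#' @param clusters Tibble from [cluster_read_ends()].
#' @param sf Optional named size factors (per sample).
#' @return Tibble: `gene_id`, `log2_shift_proximal`, `log2_shift_distal`.
#' @export
proximal_distal_shift <- function(clusters, sf = NULL) {
  usage <- differential_pas_usage(clusters, sf = sf)
  usage |>
    dplyr::filter(.data$rank %in% c("proximal", "distal")) |>
    dplyr::select("gene_id", "rank", "log2_shift") |>
    tidyr::pivot_wider(names_from = "rank", values_from = "log2_shift",
                       names_prefix = "log2_shift_")
}

#' Upstream hexamer profile around PAS anchors
#'
#' For every cluster, the `hexamer_window` nt immediately upstream of the
#' anchor are extracted in mRNA sense and scanned for the signal hexamers;
#' occurrences are aggregated by offset of the hexamer start from the anchor
#' (an occurrence ending right at the anchor has offset -6). Windows
#' truncated at a contig boundary are flagged.
#'
#' @param clusters Tibble from [cluster_read_ends()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param config An [apa_config()].
#' @return Tibble: `offset`, `hexamer`, `n`; attribute `n_truncated`.
#' @export
hexamer_enrichment <- function(clusters, genome, config = apa_config()) {
  w <- config$hexamer_window
  if (nrow(clusters) == 0L) {
    return(structure(tibble::tibble(offset = integer(), hexamer = character(),
                                    n = integer()), n_truncated = 0L))
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  len <- unname(chrom_len[clusters$chrom])
  plus <- clusters$strand == "+"
  s <- ifelse(plus, pmax(0L, clusters$anchor - w), clusters$anchor + 1L)
  e <- ifelse(plus, clusters$anchor, pmin(len, clusters$anchor + 1L + w))
  n_trunc <- sum(e - s < w)
  win <- unname(substr(as.character(genome[clusters$chrom]), s + 1L, e))
  if (any(!plus)) {
    win[!plus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(win[!plus])))
  }
  wl <- nchar(win)
  hit_list <- lapply(config$hexamer_set, function(h) {
    m <- gregexpr(h, win, fixed = TRUE)
    offs <- lapply(seq_along(m), function(i) {
      mi <- m[[i]]
      if (mi[1] == -1L) integer() else as.integer(mi) - 1L - wl[i]
    })
    offs <- unlist(offs, use.names = FALSE)
    if (length(offs) == 0L) NULL else
      tibble::tibble(offset = offs, hexamer = h)
  })
  hits <- dplyr::bind_rows(hit_list)
  out <- if (is.null(hits) || nrow(hits) == 0L) {
    tibble::tibble(offset = integer(), hexamer = character(), n = integer())
  } else {
    dplyr::count(hits, .data$offset, .data$hexamer, name = "n")
  }
  attr(out, "n_truncated") <- n_trunc
  out
}
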