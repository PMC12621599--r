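# PAS clustering, feature assignment, Fisher-exact differential usage and
# hexamer profiling.

make_cluster_reads <- function() {
  # one plus-strand gene with two well-separated end clusters
  tibble::tibble(
    read_id = sprintf("r%02d", 1:20),
    transcript_id = "t1",
    sample_id = rep(c("c1", "c2", "s1", "s2"), 5L),
    condition = rep(c("control", "control", "stimulated", "stimulated"), 5L),
    tail_length = 50L, tail_seq = strrep("A", 50L),
    end_pos = c(rep(100L, 6L), rep(102L, 2L), rep(300L, 10L), 301L, 299L),
    qc_tag = "PASS")
}

make_cluster_tx <- function(strand = "+") {
  tibble::tibble(
    gene_id = "g1", transcript_id = "t1", chrom = "c1", strand = strand,
    tx_start = 0L, tx_end = 400L,
    exons = list(cbind(start = 0L, end = 400L)),
    utr3_start = 200L, utr3_end = 400L)
}

test_that("read ends cluster by single linkage with the configured gap", {
  cl <- cluster_read_ends(make_cluster_reads(), make_cluster_tx())
  expect_identical(nrow(cl), 2L)
  expect_identical(cl$pas_id, c("g1:PAS1", "g1:PAS2"))
  expect_identical(cl$span_start, c(100L, 299L))
  expect_identical(cl$span_end, c(103L, 302L))
  expect_identical(cl$support_total, c(8L, 12L))
  expect_identical(cl$support_control, c(4L, 6L))
  expect_identical(cl$support_stimulated, c(4L, 6L))
  # modal end positions win: 100 (6 reads) and 300 (10 reads)
  expect_identical(cl$anchor, c(100L, 300L))
  bys <- cl$support_by_sample[[1]]
  expect_identical(sum(bys$n), 8L)
  expect_identical(bys$n[bys$sample_id == "c1"], 2L)
})

test_that("modal ties break to the 3'-most position in mRNA orientation", {
  reads <- make_cluster_reads()[1:8, ]
  reads$end_pos <- rep(c(100L, 104L), each = 4L)  # tied modes
  plus <- cluster_read_ends(reads, make_cluster_tx("+"))
  expect_identical(plus$anchor, 104L)
  minus <- cluster_read_ends(reads, make_cluster_tx("-"))
  expect_identical(minus$anchor, 100L)
})

test_that("clustering is invariant to read input order", {
  reads <- make_cluster_reads()
  set.seed(7)
  shuffled <- reads[sample.int(nrow(reads)), ]
  expect_identical(cluster_read_ends(reads, make_cluster_tx()),
                   cluster_read_ends(shuffled, make_cluster_tx()))
})

test_that("clusters below min_support are dropped", {
  reads <- make_cluster_reads()
  cfg <- apa_config(min_support = 9L)
  cl <- cluster_read_ends(reads, make_cluster_tx(), cfg)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$anchor, 300L)
  # a gap larger than cluster_gap splits; a gap equal to it does not
  reads2 <- make_cluster_reads()
  reads2$end_pos <- c(rep(100L, 10L), rep(124L, 10L))
  expect_identical(nrow(cluster_read_ends(reads2, make_cluster_tx())), 1L)
  reads2$end_pos <- c(rep(100L, 10L), rep(125L, 10L))
  expect_identical(nrow(cluster_read_ends(reads2, make_cluster_tx())), 2L)
})

test_that("feature assignment follows the documented precedence", {
  tx <- make_cluster_tx()
  tx$exons <- list(cbind(start = c(0L, 250L), end = c(150L, 400L)))
  tx$utr3_start <- 300L; tx$utr3_end <- 400L
  cl <- tibble::tibble(pas_id = sprintf("p%d", 1:4), gene_id = "g1",
                       chrom = "c1", strand = "+",
                       anchor = c(350L, 100L, 200L, 450L))
  got <- assign_pas_features(cl, tx)$feature
  expect_identical(got, c("three_prime_utr", "exon", "intron", "unassigned"))
  # within_transcript when the span matches but no 3'UTR is annotated
  tx2 <- tx
  tx2$utr3_start <- NA_integer_; tx2$utr3_end <- NA_integer_
  got2 <- assign_pas_features(cl[3, ], tx2)$feature
  expect_identical(got2, "within_transcript")
})

test_that("fisher_exact matches the hand-derived 34/70 example and the oracle", {
  expect_equal(fisher_exact(matrix(c(3L, 1L, 1L, 3L), 2L)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(3L, 1L, 1L, 3L), 2L)),
               stats::fisher.test(matrix(c(3L, 1L, 1L, 3L), 2L))$p.value,
               tolerance = 1e-12)
  deg <- fisher_exact(matrix(c(0L, 0L, 5L, 7L), 2L))
  expect_identical(as.numeric(deg), 1)
  expect_true(attr(deg, "degenerate"))
})

test_that("fisher_exact equals enumeration on random tables", {
  set.seed(601)
  for (rep in 1:50) {
    tab <- matrix(sample(0:10, 4L, replace = TRUE), 2L)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab),
                 oracle_fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
})

test_that("differential PAS usage builds the right 2x2 tables", {
  cl <- cluster_read_ends(make_cluster_reads(), make_cluster_tx())
  usage <- differential_pas_usage(cl)
  expect_identical(nrow(usage), 2L)
  u1 <- usage[usage$pas_id == "g1:PAS1", ]
  expect_identical(u1$pas_control, 4L)
  expect_identical(u1$others_control, 6L)
  expect_identical(u1$pas_stimulated, 4L)
  expect_identical(u1$others_stimulated, 6L)
  expect_equal(u1$p_raw,
               fisher_exact(matrix(c(4L, 4L, 6L, 6L), 2L)), tolerance = 1e-12)
  expect_equal(usage$p_adj, oracle_bh(usage$p_raw), tolerance = 1e-12)
  expect_identical(u1$rank, "proximal")
  expect_identical(usage$rank[usage$pas_id == "g1:PAS2"], "distal")
})

test_that("proximal/distal ranks flip on the minus strand", {
  cl <- cluster_read_ends(make_cluster_reads(), make_cluster_tx("-"))
  usage <- differential_pas_usage(cl)
  # smaller genomic coordinate is 3'-most (distal) on the minus strand
  expect_identical(usage$rank[order(usage$pas_id)], c("distal", "proximal"))
})

test_that("single-PAS genes are not tested", {
  reads <- make_cluster_reads()
  reads$end_pos <- 100L
  cl <- cluster_read_ends(reads, make_cluster_tx())
  expect_message(usage <- differential_pas_usage(cl), "nothing to test")
  expect_identical(nrow(usage), 0L)
})

test_that("log2_shift uses size-factor-normalized support when given", {
  cl <- cluster_read_ends(make_cluster_reads(), make_cluster_tx())
  sf <- c(c1 = 1, c2 = 1, s1 = 2, s2 = 2)
  usage <- differential_pas_usage(cl, sf = sf)
  u1 <- usage[usage$pas_id == "g1:PAS1", ]
  # raw support 4 vs 4; stim samples are halved by their size factor 2
  expect_equal(u1$log2_shift, log2((2 + 0.5) / (4 + 0.5)), tolerance = 1e-12)
  shifts <- proximal_distal_shift(cl, sf = sf)
  expect_identical(names(shifts),
                   c("gene_id", "log2_shift_proximal", "log2_shift_distal"))
  expect_equal(shifts$log2_shift_proximal, u1$log2_shift, tolerance = 1e-12)
})

test_that("hexamer profile recovers a planted AATAAA at its offset", {
  # plus strand: anchor 50, AATAAA planted so its start is 20 nt upstream
  seq_p <- strrep("C", 60)
  substr(seq_p, 31, 36) <- "AATAAA"   # 1-based 31..36 -> offset -20 from anchor 50
  genome <- Biostrings::DNAStringSet(c(c1 = seq_p))
  cl <- tibble::tibble(pas_id = "p1", gene_id = "g1", chrom = "c1",
                       strand = "+", anchor = 50L)
  prof <- hexamer_enrichment(cl, genome)
  expect_identical(nrow(prof), 1L)
  expect_identical(prof$offset, -20L)
  expect_identical(prof$hexamer, "AATAAA")
  expect_identical(prof$n, 1L)
  expect_identical(attr(prof, "n_truncated"), 0L)
})

test_that("hexamer profile reads the minus strand in mRNA sense", {
  # minus strand: upstream of anchor a is genomic [a+1, a+1+w), revcomped.
  # place TTTATT at genomic 11..16 so the mRNA-sense window shows AATAAA
  seq_m <- strrep("G", 60)
  substr(seq_m, 11, 16) <- "TTTATT"
  genome <- Biostrings::DNAStringSet(c(c1 = seq_m))
  cl <- tibble::tibble(pas_id = "p1", gene_id = "g1", chrom = "c1",
                       strand = "-", anchor = 5L)
  prof <- hexamer_enrichment(cl, genome, apa_config(hexamer_window = 20L))
  expect_identical(prof$hexamer, "AATAAA")
  expect_identical(prof$n, 1L)
})

test_that("simulated two-PAS genes concentrate the hexamer at -20", {
  d <- simulate_dataset(sim_config(seed = 61L, n_genes = 40L))
  cl <- cluster_read_ends(d$reads, d$transcripts)
  prof <- hexamer_enrichment(cl, d$genome)
  expect_identical(prof$offset[which.max(prof$n)], -20L)
})
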