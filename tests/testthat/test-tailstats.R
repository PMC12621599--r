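# Rank-sum machinery, BH, effect sizes, and the per-transcript test,
# validated against independent oracles and hand computations.

test_that("exact rank-sum p matches full enumeration on fixed cases", {
  # complete separation, nx = ny = 3: U = 0, p = 2/20 = 0.1
  rs <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_identical(rs$U, 0)
  expect_equal(rs$p, 0.1, tolerance = 1e-12)
  expect_equal(rs$p, oracle_ranksum_exact(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  # interleaved case
  x <- c(1.5, 3.2, 7.1); y <- c(2.0, 4.4, 5.5, 9.9)
  rs2 <- ranksum_test(x, y)
  expect_equal(rs2$p, oracle_ranksum_exact(x, y), tolerance = 1e-12)
})

test_that("exact rank-sum p matches enumeration across random small groups", {
  set.seed(401)
  for (rep in 1:40) {
    nx <- sample(1:6, 1); ny <- sample(1:6, 1)
    vals <- sample(1000L, nx + ny)  # distinct -> no ties
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(ranksum_test(x, y)$p, oracle_ranksum_exact(x, y),
                 tolerance = 1e-12,
                 label = sprintf("nx=%d ny=%d", nx, ny))
  }
})

test_that("rank-sum U is the Mann-Whitney count of (x < y) pairs", {
  set.seed(402)
  for (rep in 1:20) {
    x <- sample(1000L, 5); y <- sample(1000L, 7)
    u <- ranksum_test(x, y)$U
    expect_identical(u, sum(outer(x, y, ">")) + 0)
  }
})

test_that("rank-sum falls back to the tie-corrected normal approximation", {
  x <- rep(c(1, 2, 3), 5); y <- rep(c(2, 3, 4), 5)
  rs <- ranksum_test(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(rs$p, ref$p.value, tolerance = 1e-10)
  # all values tied: no information, p = 1
  expect_identical(ranksum_test(rep(1, 10), rep(1, 12))$p, 1)
})

test_that("rank-sum agrees with stats::wilcox.test on the exact path", {
  set.seed(403)
  for (rep in 1:20) {
    vals <- sample(10000L, 14)      # distinct across both groups
    x <- vals[1:6]; y <- vals[7:14]
    rs <- ranksum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(rs$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the definitional computation", {
  set.seed(404)
  for (rep in 1:25) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, NA)), "0, 1")
})

test_that("Cohen's d matches the hand computation", {
  # means 10 vs 12, pooled variance 2 -> d = 2 / sqrt(2) = sqrt(2)
  expect_equal(cohens_d(c(9, 11), c(11, 13)), sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(c(11, 13), c(9, 11)), -sqrt(2), tolerance = 1e-12)
  d0 <- cohens_d(c(5, 5), c(5, 5))
  expect_identical(as.numeric(d0), 0)
  expect_true(attr(d0, "degenerate"))
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("effect-size bins are lower-inclusive at 0.2 / 0.5 / 0.8", {
  d <- c(0, 0.1999999, 0.2, 0.4999999, 0.5, 0.7999999, 0.8, 3,
         -0.2, -0.5, -0.8)
  expect_identical(
    classify_effect_size(d),
    c("negligible", "negligible", "small", "small", "medium", "medium",
      "large", "large", "small", "medium", "large"))
})

test_that("differential_adenylation reproduces a by-hand analysis", {
  reads <- make_toy_reads()
  res <- differential_adenylation(reads, tail_test_config(min_reads = 6L))
  expect_identical(sort(res$transcript_id), c("txA", "txB"))
  a <- res[res$transcript_id == "txA", ]
  # control 40..60 step 4, stimulated 90..110 step 4
  expect_identical(a$n_control, 6L)
  expect_identical(a$median_control, 50)
  expect_identical(a$median_stimulated, 100)
  expect_identical(a$delta_median, 50)
  expect_equal(a$delta_mean, 50, tolerance = 1e-12)
  expect_equal(a$p_raw, oracle_ranksum_exact(
    c(40, 44, 48, 52, 56, 60), c(90, 94, 98, 102, 106, 110)), tolerance = 1e-12)
  expect_equal(res$p_adj, oracle_bh(res$p_raw)[order(res$transcript_id)],
               tolerance = 1e-14)
  expect_true(a$significant)
  b <- res[res$transcript_id == "txB", ]
  expect_false(b$significant)
  expect_identical(a$effect_class, "large")
})

test_that("the per-condition minimum of 10 reads is enforced exactly", {
  base <- make_toy_reads()[make_toy_reads()$transcript_id == "txA", ]
  mk <- function(n_ctrl, n_stim) {
    tibble::tibble(
      read_id = sprintf("r%03d", seq_len(n_ctrl + n_stim)),
      transcript_id = "tx",
      sample_id = rep(c("c1", "s1"), c(n_ctrl, n_stim)),
      condition = rep(c("control", "stimulated"), c(n_ctrl, n_stim)),
      tail_length = c(seq_len(n_ctrl) * 3L + 10L, seq_len(n_stim) * 3L + 60L),
      tail_seq = "", end_pos = 0L, qc_tag = "PASS")
  }
  expect_identical(nrow(differential_adenylation(mk(10L, 10L))), 1L)
  expect_warning(out <- differential_adenylation(mk(9L, 10L)), "threshold")
  expect_identical(nrow(out), 0L)
  expect_warning(out2 <- differential_adenylation(mk(10L, 9L)), "threshold")
  expect_identical(nrow(out2), 0L)
})

test_that("dual significance needs |delta median| strictly above 5 nt", {
  mk_shift <- function(delta) {
    vals <- rep(1:20, each = 10L)   # median 10.5, plenty of power at n = 200
    n <- length(vals)
    tibble::tibble(
      read_id = sprintf("r%03d", seq_len(2L * n)),
      transcript_id = "tx",
      sample_id = rep(c("c1", "s1"), each = n),
      condition = rep(c("control", "stimulated"), each = n),
      tail_length = c(vals, vals + delta),
      tail_seq = "", end_pos = 0L, qc_tag = "PASS")
  }
  at5 <- differential_adenylation(mk_shift(5L))
  expect_identical(at5$delta_median, 5)
  expect_lt(at5$p_adj, 0.05)       # plainly significant p, yet...
  expect_false(at5$significant)    # ...blocked by the 5 nt threshold
  at6 <- differential_adenylation(mk_shift(6L))
  expect_identical(at6$delta_median, 6)
  expect_true(at6$significant)
})

test_that("FAIL reads are excluded before testing", {
  reads <- make_toy_reads()
  reads$qc_tag[reads$transcript_id == "txA" & reads$condition == "control"] <- "FAIL"
  res <- differential_adenylation(reads, tail_test_config(min_reads = 6L))
  expect_identical(res$transcript_id, "txB")
})

test_that("composition_summary counts decorated tails and bases by hand", {
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:5),
    transcript_id = c("t1", "t1", "t1", "t2", "t2"),
    sample_id = "s1", condition = "control",
    tail_length = c(4L, 4L, 6L, 8L, 5L),
    tail_seq = c("AAAA", "AGAA", "AAGCTA", "AAAAAAAA", ""),
    end_pos = 0L, qc_tag = c("PASS", "PASS", "SUFFCLIP", "PASS", "PASS"))
  reads$tail_length[5] <- 0L
  glob <- composition_summary(reads)
  expect_identical(glob$n_reads, 4L)
  expect_identical(glob$n_no_seq, 1L)
  expect_identical(glob$n_decorated, 2L)
  expect_equal(glob$frac_decorated, 0.5)
  expect_identical(glob$n_G, 2L)
  expect_identical(glob$n_C, 1L)
  expect_identical(glob$n_U, 1L)
  hist <- glob$nonA_histogram[[1]]
  expect_identical(hist$n_reads[hist$n_nonA == 0L], 2L)
  expect_identical(hist$n_reads[hist$n_nonA == 1L], 1L)
  expect_identical(hist$n_reads[hist$n_nonA == 3L], 1L)
  by_tx <- composition_summary(reads, group_by = "transcript_id")
  expect_identical(by_tx$n_decorated[by_tx$scope == "t1"], 2L)
  expect_identical(by_tx$n_decorated[by_tx$scope == "t2"], 0L)
  expect_identical(by_tx$n_no_seq[by_tx$scope == "t2"], 1L)
})
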