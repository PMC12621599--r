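# Independent oracles used to validate the package's statistical machinery.
# Each is written from the textbook definition, sharing no code with the
# implementations under test.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Two-sided exact rank-sum p-value by full enumeration of rank assignments.
# For distinct values: U = (rank sum of x) - nx(nx+1)/2; the two-sided p
# doubles the smaller tail of the exact permutation distribution (capped at 1).
oracle_ranksum_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  assignments <- utils::combn(nx + ny, nx)
  u_all <- apply(assignments, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Two-sided Fisher exact p by enumeration of all tables with the observed
# margins: sum hypergeometric point probabilities not exceeding the observed
# one (conventional 1 + 1e-7 tolerance).
oracle_fisher_exact <- function(a, b, cc, d) {
  m <- a + b          # row 1 total
  n <- cc + d         # row 2 total
  k <- a + cc         # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg from the definition: q_(i) = min_{j >= i} p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * n / seq_len(n))))
  q_sorted <- pmin(1, q_sorted)
  out <- numeric(n)
  out[ord] <- q_sorted
  out
}

# Exact PWM score p-values by exhaustive enumeration of all 4^W words:
# P(integer score >= t) under the 0-order background model.
oracle_pwm_pvalue <- function(int_scores, background, t) {
  w <- nrow(int_scores)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  score <- numeric(nrow(words))
  prob <- rep(1, nrow(words))
  for (i in seq_len(w)) {
    score <- score + int_scores[i, words[, i]]
    prob <- prob * background[words[, i]]
  }
  vapply(t, function(tt) sum(prob[score >= tt]), numeric(1))
}

# Small crafted read table used across tests: two transcripts, two samples
# per condition, fully deterministic.
make_toy_reads <- function() {
  tibble::tibble(
    read_id = sprintf("r%02d", 1:24),
    transcript_id = rep(c("txA", "txB"), each = 12L),
    sample_id = rep(rep(c("ctrl_1", "ctrl_2", "stim_1", "stim_2"), each = 3L), 2L),
    condition = rep(rep(c("control", "stimulated"), each = 6L), 2L),
    tail_length = c(
      40L, 44L, 48L, 52L, 56L, 60L, 90L, 94L, 98L, 102L, 106L, 110L,
      60L, 61L, 62L, 63L, 64L, 65L, 60L, 61L, 62L, 63L, 64L, 66L),
    tail_seq = strrep("A", c(
      40L, 44L, 48L, 52L, 56L, 60L, 90L, 94L, 98L, 102L, 106L, 110L,
      60L, 61L, 62L, 63L, 64L, 65L, 60L, 61L, 62L, 63L, 64L, 66L)),
    end_pos = 399L,
    qc_tag = "PASS")
}
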