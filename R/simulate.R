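# Seeded synthetic-data generator.
#
# Emits a genome (one contig per gene), a GTF-lite-style annotation, a
# per-read tail table and a ground-truth object. Five per-gene mechanisms are
# planted: null, transcriptional induction (more reads, with the *excess*
# molecules carrying long tails), cytoplasmic polyadenylation (same
# abundance, all stimulated tails elongated), deadenylation-coupled decay
# (fewer reads, shorter tails) and translation-coupled deadenylation (same
# abundance, mildly shorter tails). On top of these: two-PAS genes with a
# condition-dependent proximal/distal usage split, per-position tail
# "decoration" (non-adenosine misincorporation) whose per-read probability
# rises with tail length, and semi-templated genes whose A/T-rich genomic
# 3'UTR terminus is fused into the tail at fixed offsets.

MECHANISMS <- c("null", "transcriptional_induction", "cytoplasmic_polyadenylation",
                "deadenylation_decay", "translation_deadenylation")

#' Simulation configuration
#'
#' Defaults define the package's reference simulation: 500 genes with a
#' 50/50/50/350 split of induction / cytoplasmic polyadenylation /
#' deadenylation-decay / null mechanisms, 4 replicates per condition at a
#' mean depth of 12.5 reads per gene per sample (about 50 reads per gene per
#' condition), lognormal tails with a 60-nt baseline median and 0.35 log-sd,
#' a 4-fold induction, a 40-nt tail shift, a 0.002 per-nt misincorporation
#' rate with G >= C >= U bias, 30% two-PAS genes with proximal usage moving
#' 0.3 -> 0.6 on stimulation, and 10% semi-templated genes.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_genes Number of genes (one contig each).
#' @param n_replicates Replicates per condition.
#' @param baseline_mean_expression Mean reads per gene per sample (NB mean).
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param baseline_tail_median Baseline poly(A) tail median, nt.
#' @param tail_sd_log Lognormal sd of tail lengths (log scale).
#' @param mechanism_fractions Named fractions over the five mechanisms.
#' @param mechanism_assignments Optional named character vector gene_id ->
#'   mechanism, overriding `mechanism_fractions`.
#' @param induction_fold Abundance fold for induction / decay (> 1).
#' @param tail_shift Tail median shift, nt.
#' @param epsilon Per-nt probability of a non-adenosine misincorporation.
#' @param nonA_bias Named probabilities over G, C, T (must be G >= C >= T).
#' @param frac_two_pas Fraction of genes carrying a second (proximal) PAS.
#' @param proximal_usage Length-2 vector: proximal-PAS usage probability in
#'   (control, stimulated).
#' @param frac_semitemplated Fraction of genes with an A/T-rich 3'UTR
#'   terminus fused into the tail.
#' @param utr_at_fraction_rich Terminal A/T fraction for semi-templated
#'   genes, in (0.6, 1].
#' @param utr_at_fraction_background Background terminal A/T fraction, < 0.6.
#' @param end_jitter_sd Genomic 3'-end jitter sd, nt (clamped to +/- 6).
#' @param qc_probs Probabilities of PASS / SUFFCLIP / FAIL tags per read.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 500L,
                       n_replicates = 4L,
                       baseline_mean_expression = 12.5,
                       nb_dispersion = 0.05,
                       baseline_tail_median = 60,
                       tail_sd_log = 0.35,
                       mechanism_fractions = c(
                         null = 0.70, transcriptional_induction = 0.10,
                         cytoplasmic_polyadenylation = 0.10,
                         deadenylation_decay = 0.10,
                         translation_deadenylation = 0.00),
                       mechanism_assignments = NULL,
                       induction_fold = 4,
                       tail_shift = 40,
                       epsilon = 0.002,
                       nonA_bias = c(G = 0.5, C = 0.3, T = 0.2),
                       frac_two_pas = 0.3,
                       proximal_usage = c(control = 0.3, stimulated = 0.6),
                       frac_semitemplated = 0.1,
                       utr_at_fraction_rich = 0.85,
                       utr_at_fraction_background = 0.45,
                       end_jitter_sd = 2,
                       qc_probs = c(PASS = 0.90, SUFFCLIP = 0.08, FAIL = 0.02)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              baseline_mean_expression = baseline_mean_expression,
              nb_dispersion = nb_dispersion,
              baseline_tail_median = baseline_tail_median,
              tail_sd_log = tail_sd_log,
              mechanism_fractions = mechanism_fractions,
              mechanism_assignments = mechanism_assignments,
              induction_fold = induction_fold, tail_shift = tail_shift,
              epsilon = epsilon, nonA_bias = nonA_bias,
              frac_two_pas = frac_two_pas, proximal_usage = proximal_usage,
              frac_semitemplated = frac_semitemplated,
              utr_at_fraction_rich = utr_at_fraction_rich,
              utr_at_fraction_background = utr_at_fraction_background,
              end_jitter_sd = end_jitter_sd, qc_probs = qc_probs)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L, cfg$n_replicates >= 1L,
            cfg$baseline_mean_expression > 0, cfg$nb_dispersion > 0,
            cfg$baseline_tail_median > 0, cfg$tail_sd_log > 0,
            cfg$induction_fold > 1, cfg$tail_shift >= 0,
            cfg$epsilon >= 0, cfg$epsilon <= 1)
  if (is.null(cfg$mechanism_assignments)) {
    mf <- cfg$mechanism_fractions
    if (!all(names(mf) %in% MECHANISMS) || abs(sum(mf) - 1) > 1e-8 || any(mf < 0)) {
      stop("mechanism_fractions must be nonnegative, named over the five mechanisms, and sum to 1")
    }
  } else if (!all(cfg$mechanism_assignments %in% MECHANISMS)) {
    stop("unknown mechanism in mechanism_assignments")
  }
  nb <- cfg$nonA_bias
  if (!identical(sort(names(nb)), c("C", "G", "T")) || abs(sum(nb) - 1) > 1e-8) {
    stop("nonA_bias must be named probabilities over G, C, T summing to 1")
  }
  if (!(nb["G"] >= nb["C"] && nb["C"] >= nb["T"])) {
    stop("nonA_bias must satisfy G >= C >= T")
  }
  if (cfg$frac_two_pas < 0 || cfg$frac_two_pas > 1 ||
      cfg$frac_semitemplated < 0 || cfg$frac_semitemplated > 1) {
    stop("fractions must lie in [0, 1]")
  }
  if (any(cfg$proximal_usage < 0) || any(cfg$proximal_usage > 1)) {
    stop("proximal_usage must lie in [0, 1]")
  }
  if (cfg$utr_at_fraction_rich <= 0.6 || cfg$utr_at_fraction_rich > 1) {
    stop("utr_at_fraction_rich must lie in (0.6, 1]")
  }
  if (cfg$utr_at_fraction_background >= 0.6 || cfg$utr_at_fraction_background < 0) {
    stop("utr_at_fraction_background must lie in [0, 0.6)")
  }
  invisible(cfg)
}

# stable per-gene sub-seed so adding genes does not reshuffle existing ones
gene_seed <- function(seed, gene_id, stage) {
  s <- paste0(gene_id, "/", stage)
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + as.numeric(seed) * 97003) %% 2147483647)
}

# layout constants (mRNA-sense transcript coordinates)
SIM_TX_LEN <- 400L       # single-exon transcript length
SIM_UTR_LEN <- 200L      # 3'UTR length (>= 80 per contract)
SIM_PAD <- 100L          # contig padding on the 5' genomic side
SIM_PAD3 <- 50L          # contig padding on the 3' genomic side
SIM_PROX_OFFSET <- 150L  # proximal PAS distance upstream of the distal end
SIM_SEMI_SUFFIX <- 18L   # genomic nt fused into semi-templated tails
HEXAMER <- "AATAAA"

max_at_run_chr <- function(chars) {
  at <- chars %in% c("A", "T")
  if (!any(at)) return(0L)
  r <- rle(at)
  max(r$lengths[r$values])
}

window_passes_rules <- function(chars) {
  # semi-templated screening rules on a terminal window
  frac <- mean(chars %in% c("A", "T"))
  run <- max_at_run_chr(chars)
  frac > 0.6 || run > 10L  # conservative: background must also avoid runs 11-12
}

sample_bases <- function(n, at_fraction) {
  at <- stats::runif(n) < at_fraction
  out <- character(n)
  out[at] <- sample(c("A", "T"), sum(at), replace = TRUE, prob = c(0.6, 0.4))
  out[!at] <- sample(c("G", "C"), sum(!at), replace = TRUE, prob = c(0.55, 0.45))
  out
}

#' Generate the synthetic reference (genome + annotation)
#'
#' One contig per gene; each transcript is single-exon with a 200-nt 3'UTR.
#' Semi-templated genes receive an A/T-rich terminal 60 nt with a
#' guaranteed 13-nt-or-longer terminal A/T run; all other genes are constructed so that no
#' candidate terminal window (annotated end or any called PAS, including
#' end-position jitter) passes either semi-templated screening rule. Two-PAS
#' genes get a proximal PAS 150 nt upstream of the distal end; a canonical
#' AATAAA is planted 20 nt upstream of every (non-semi-templated) PAS anchor.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `transcripts`
#'   (annotation tibble) and `gene_info` (per-gene layout + mechanism table).
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n))

  set.seed(config$seed)
  if (is.null(config$mechanism_assignments)) {
    counts <- floor(config$mechanism_fractions * n)
    counts["null"] <- counts["null"] + (n - sum(counts))
    mech_pool <- rep(names(counts), counts)
    mech <- sample(mech_pool, n)
  } else {
    if (!all(gene_ids %in% names(config$mechanism_assignments))) {
      stop("mechanism_assignments must cover all genes (ids g0001..)")
    }
    mech <- unname(config$mechanism_assignments[gene_ids])
  }
  strand <- rep(c("+", "-"), length.out = n)

  n_semi <- round(config$frac_semitemplated * n)
  n_two <- round(config$frac_two_pas * n)
  null_idx <- which(mech == "null")
  other_idx <- setdiff(seq_len(n), null_idx)
  if (n_semi > length(null_idx)) {
    stop("frac_semitemplated exceeds the available null-mechanism genes")
  }
  semi_idx <- null_idx[seq_len(n_semi)]
  two_pool <- c(setdiff(null_idx, semi_idx), setdiff(other_idx, semi_idx))
  if (n_two > length(two_pool)) stop("frac_two_pas too large given frac_semitemplated")
  two_idx <- two_pool[seq_len(n_two)]

  is_semi <- seq_len(n) %in% semi_idx
  is_two <- seq_len(n) %in% two_idx

  tx_len <- SIM_TX_LEN
  seqs <- character(n)
  for (i in seq_len(n)) {
    set.seed(gene_seed(config$seed, gene_ids[i], "ref"))
    body <- sample_bases(tx_len, config$utr_at_fraction_background)
    if (is_semi[i]) {
      term <- sample_bases(60L, config$utr_at_fraction_rich)
      # fixed terminus: ...AATG + 16 A -> an 18-nt genomic suffix (TG + 16A)
      # fused into tails, a >= 16-nt terminal A/T run, last 3 nt A/T
      term[41:60] <- c("A", "A", "T", "G", rep("A", 16L))
      body[(tx_len - 59L):tx_len] <- term
    } else {
      # regenerate the candidate-window region until every window that the
      # semi-templated caller could examine fails both screening rules
      reg_start <- tx_len - 217L + 1L  # 1-based mRNA index
      repeat {
        body[reg_start:tx_len] <- sample_bases(217L, config$utr_at_fraction_background)
        # plant the polyadenylation signal 20 nt upstream of each anchor
        a_dist <- tx_len            # 1-based index of the last templated base
        body[(a_dist - 20L):(a_dist - 15L)] <- strsplit(HEXAMER, "")[[1]]
        anchors <- a_dist
        if (is_two[i]) {
          a_prox <- tx_len - SIM_PROX_OFFSET
          body[(a_prox - 20L):(a_prox - 15L)] <- strsplit(HEXAMER, "")[[1]]
          anchors <- c(anchors, a_prox)
        }
        ok <- TRUE
        for (a in anchors) {
          for (e in (a - 8L):min(a + 8L, tx_len)) {
            if (window_passes_rules(body[(e - 59L):e])) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) break
      }
    }
    mrna <- paste(body, collapse = "")
    pad5 <- paste(sample_bases(SIM_PAD, 0.5), collapse = "")
    pad3 <- paste(sample_bases(SIM_PAD3, 0.5), collapse = "")
    if (strand[i] == "+") {
      seqs[i] <- paste0(pad5, mrna, pad3)
    } else {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mrna)))
      seqs[i] <- paste0(pad3, rc, pad5)
    }
  }

  chrom <- paste0("chr_", gene_ids)
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chrom

  tx_start <- ifelse(strand == "+", SIM_PAD, SIM_PAD3)
  tx_end <- tx_start + tx_len
  utr3_start <- ifelse(strand == "+", tx_end - SIM_UTR_LEN, tx_start)
  utr3_end <- ifelse(strand == "+", tx_end, tx_start + SIM_UTR_LEN)

  # genomic coordinate of mRNA index i (0-based): + -> tx_start + i ; - -> tx_end - 1 - i
  mrna2genome <- function(i, s, ts, te) ifelse(s == "+", ts + i, te - 1L - i)
  a_dist_m <- tx_len - 1L
  a_prox_m <- tx_len - 1L - SIM_PROX_OFFSET
  a_semi_m <- tx_len - 1L - SIM_SEMI_SUFFIX

  gene_info <- tibble::tibble(
    gene_id = gene_ids,
    transcript_id = paste0(gene_ids, ".t1"),
    chrom = chrom, strand = strand, mechanism = mech,
    is_two_pas = is_two, is_semitemplated = is_semi,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    utr3_start = as.integer(utr3_start), utr3_end = as.integer(utr3_end),
    pas_distal = as.integer(mrna2genome(a_dist_m, strand, tx_start, tx_end)),
    pas_proximal = ifelse(is_two,
      as.integer(mrna2genome(a_prox_m, strand, tx_start, tx_end)), NA_integer_),
    anchor_read = as.integer(ifelse(is_semi,
      mrna2genome(a_semi_m, strand, tx_start, tx_end),
      mrna2genome(a_dist_m, strand, tx_start, tx_end)))
  )

  transcripts <- tibble::tibble(
    gene_id = gene_info$gene_id, transcript_id = gene_info$transcript_id,
    chrom = gene_info$chrom, strand = gene_info$strand,
    tx_start = gene_info$tx_start, tx_end = gene_info$tx_end,
    exons = purrr::map2(gene_info$tx_start, gene_info$tx_end,
                        ~cbind(start = .x, end = .y)),
    utr3_start = gene_info$utr3_start, utr3_end = gene_info$utr3_end
  )

  list(genome = genome, transcripts = transcripts, gene_info = gene_info)
}

decorate_tails <- function(lens, epsilon, bias) {
  # returns list(seq = character, pos = list of decorated positions)
  n <- length(lens)
  seqs <- strrep("A", lens)
  pos <- vector("list", n)
  nmut <- stats::rbinom(n, lens, epsilon)
  for (j in which(nmut > 0L)) {
    p <- sort(sample.int(lens[j], nmut[j]))
    chars <- strsplit(seqs[j], "")[[1]]
    chars[p] <- sample(names(bias), nmut[j], replace = TRUE, prob = bias)
    seqs[j] <- paste(chars, collapse = "")
    pos[[j]] <- p
  }
  list(seq = seqs, pos = pos)
}

#' Generate synthetic reads and ground truth
#'
#' @param config A [sim_config()].
#' @param reference Output of [generate_reference()].
#' @return List with `reads` (per-read tibble, the tail-table schema) and
#'   `truth` (a `sim_truth` list: per-gene mechanisms/effects/PAS usage and
#'   per-read decorated positions).
#' @export
generate_reads <- function(config, reference) {
  validate_sim_config(config)
  gi <- reference$gene_info
  fold <- config$induction_fold
  m0 <- config$baseline_tail_median
  shift <- config$tail_shift
  sdl <- config$tail_sd_log
  reps <- config$n_replicates
  samples <- list(control = paste0("ctrl_", seq_len(reps)),
                  stimulated = paste0("stim_", seq_len(reps)))

  chunks <- vector("list", nrow(gi) * 2L * reps)
  n_chunks <- 0L
  for (i in seq_len(nrow(gi))) {
    g <- gi[i, ]
    set.seed(gene_seed(config$seed, g$gene_id, "reads"))
    for (cond in c("control", "stimulated")) {
      mu <- config$baseline_mean_expression
      if (cond == "stimulated") {
        if (g$mechanism == "transcriptional_induction") mu <- mu * fold
        if (g$mechanism == "deadenylation_decay") mu <- mu / fold
      }
      for (s in samples[[cond]]) {
        k <- stats::rnbinom(1L, mu = mu, size = 1 / config$nb_dispersion)
        if (k == 0L) next
        med <- m0
        is_new <- rep(FALSE, k)
        if (cond == "stimulated") {
          med <- switch(g$mechanism,
            null = m0,
            transcriptional_induction = m0,  # per-read mixture below
            cytoplasmic_polyadenylation = m0 + shift,
            deadenylation_decay = max(m0 - shift, 5),
            translation_deadenylation = max(m0 - shift / 4, 5))
          if (g$mechanism == "transcriptional_induction") {
            is_new <- stats::runif(k) < (fold - 1) / fold
          }
        }
        meds <- rep(med, k)
        meds[is_new] <- m0 + shift
        lens <- pmax(1L, as.integer(round(stats::rlnorm(k, log(meds), sdl))))

        # 3'-end positions
        if (g$is_semitemplated) {
          end_pos <- rep(g$anchor_read, k)
          use_prox <- rep(FALSE, k)
        } else if (g$is_two_pas) {
          use_prox <- stats::runif(k) < unname(config$proximal_usage[[cond]])
          anchors <- ifelse(use_prox, g$pas_proximal, g$pas_distal)
          jit <- pmin(pmax(round(stats::rnorm(k, 0, config$end_jitter_sd)), -6L), 6L)
          end_pos <- anchors + jit
          # clamp within the transcript span
          end_pos <- pmin(pmax(end_pos, g$tx_start), g$tx_end - 1L)
        } else {
          jit <- pmin(pmax(round(stats::rnorm(k, 0, config$end_jitter_sd)), -6L), 6L)
          end_pos <- pmin(pmax(g$pas_distal + jit, g$tx_start), g$tx_end - 1L)
          use_prox <- rep(FALSE, k)
        }

        dec <- decorate_tails(lens, config$epsilon, config$nonA_bias)
        tails <- dec$seq
        if (g$is_semitemplated) {
          tails <- paste0("TG", strrep("A", 16L), tails)
          lens <- lens + SIM_SEMI_SUFFIX
          dec$pos <- lapply(dec$pos, function(p) if (is.null(p)) NULL else p + SIM_SEMI_SUFFIX)
        }
        qc <- sample(names(config$qc_probs), k, replace = TRUE, prob = config$qc_probs)
        n_chunks <- n_chunks + 1L
        chunks[[n_chunks]] <- list(
          read_id = paste0(g$gene_id, ":", s, ":", seq_len(k)),
          transcript_id = rep(g$transcript_id, k),
          sample_id = rep(s, k), condition = rep(cond, k),
          tail_length = lens, tail_seq = tails,
          end_pos = as.integer(end_pos), qc_tag = qc,
          decorated_positions = dec$pos
        )
      }
    }
  }
  chunks <- chunks[seq_len(n_chunks)]
  pull <- function(field) unlist(lapply(chunks, `[[`, field), use.names = FALSE)
  reads_full <- tibble::tibble(
    read_id = pull("read_id"), transcript_id = pull("transcript_id"),
    sample_id = pull("sample_id"), condition = pull("condition"),
    tail_length = pull("tail_length"), tail_seq = pull("tail_seq"),
    end_pos = pull("end_pos"), qc_tag = pull("qc_tag"),
    decorated_positions = do.call(c, lapply(chunks, `[[`, "decorated_positions"))
  )

  truth_genes <- tibble::tibble(
    gene_id = gi$gene_id, transcript_id = gi$transcript_id,
    mechanism = gi$mechanism,
    true_log2_fc = dplyr::case_when(
      gi$mechanism == "transcriptional_induction" ~ log2(fold),
      gi$mechanism == "deadenylation_decay" ~ -log2(fold),
      TRUE ~ 0),
    true_tail_shift = dplyr::case_when(
      gi$mechanism == "cytoplasmic_polyadenylation" ~ shift,
      gi$mechanism == "transcriptional_induction" ~ shift,
      gi$mechanism == "deadenylation_decay" ~ -shift,
      gi$mechanism == "translation_deadenylation" ~ -shift / 4,
      TRUE ~ 0),
    is_semitemplated = gi$is_semitemplated, is_two_pas = gi$is_two_pas,
    pas_distal = gi$pas_distal, pas_proximal = gi$pas_proximal,
    usage_proximal_control = ifelse(gi$is_two_pas,
      unname(config$proximal_usage[[1]]), NA_real_),
    usage_proximal_stimulated = ifelse(gi$is_two_pas,
      unname(config$proximal_usage[[2]]), NA_real_)
  )
  truth <- list(
    genes = truth_genes,
    reads = tibble::tibble(read_id = reads_full$read_id,
                           decorated_positions = reads_full$decorated_positions),
    seed = config$seed
  )
  class(truth) <- "sim_truth"

  reads <- reads_full[, TAIL_TABLE_COLS]
  list(reads = reads, truth = truth)
}

#' Run the full simulation
#'
#' Convenience wrapper: [generate_reference()] + [generate_reads()].
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `transcripts`, `gene_info`, `reads`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ref <- generate_reference(config)
  rd <- generate_reads(config, ref)
  c(ref, rd)
}

#' Write / read ground truth as JSON
#'
#' Keys are emitted sorted; `read_truth(write_truth(x))` restores the same
#' per-gene and per-read content.
#'
#' @param truth A `sim_truth` object.
#' @param path Output path.
#' @return `path`, invisibly (`write_truth`); a `sim_truth` (`read_truth`).
#' @export
write_truth <- function(truth, path) {
  genes <- truth$genes[order(truth$genes$gene_id), ]
  reads <- truth$reads[order(truth$reads$read_id), ]
  obj <- list(
    genes = lapply(seq_len(nrow(genes)), function(i) {
      row <- as.list(genes[i, ])
      row[sort(names(row))]
    }),
    reads = lapply(seq_len(nrow(reads)), function(i) {
      list(decorated_positions = as.integer(reads$decorated_positions[[i]]),
           read_id = reads$read_id[i])
    }),
    seed = truth$seed
  )
  obj <- obj[sort(names(obj))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  genes <- dplyr::bind_rows(lapply(obj$genes, function(g) {
    tibble::tibble(
      gene_id = g$gene_id, transcript_id = g$transcript_id,
      mechanism = g$mechanism, true_log2_fc = as.numeric(g$true_log2_fc),
      true_tail_shift = as.numeric(g$true_tail_shift),
      is_semitemplated = isTRUE(g$is_semitemplated),
      is_two_pas = isTRUE(g$is_two_pas),
      pas_distal = as.integer(g$pas_distal),
      pas_proximal = if (is.null(g$pas_proximal)) NA_integer_ else as.integer(g$pas_proximal),
      usage_proximal_control = if (is.null(g$usage_proximal_control)) NA_real_ else as.numeric(g$usage_proximal_control),
      usage_proximal_stimulated = if (is.null(g$usage_proximal_stimulated)) NA_real_ else as.numeric(g$usage_proximal_stimulated)
    )
  }))
  reads <- tibble::tibble(
    read_id = vapply(obj$reads, `[[`, "", "read_id"),
    decorated_positions = lapply(obj$reads, function(r) {
      p <- unlist(r$decorated_positions)
      if (is.null(p)) NULL else as.integer(p)
    })
  )
  truth <- list(genes = genes, reads = reads, seed = obj$seed)
  class(truth) <- "sim_truth"
  truth
}
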