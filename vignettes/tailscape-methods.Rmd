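---
title: "Methods: statistical models and the synthetic-data generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical models and the synthetic-data generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tailscape)
```

tailscape analyses mRNA 3'-end dynamics from nanopore-style per-read
poly(A) tail tables: per-transcript tail-length changes, differential
expression, alternative polyadenylation-site (PAS) usage, cytoplasmic
polyadenylation element (CPE) scanning, semi-templated tail discovery, and
a joint mechanism call per gene. This vignette documents the statistical
models, the defaults and their rationale, the synthetic-data generator, and
the numerical choices that make results exactly reproducible.

## Input model

The unit of input is a *per-read tail table*: one row per sequenced read
with `read_id`, `transcript_id`, `sample_id`, `condition`
(`control`/`stimulated`), `tail_length` (nt), `tail_seq` (the called tail
nucleotides, 5'→3'), `end_pos` (0-based transcript coordinate of the read
3' end), and `qc_tag`. Reads tagged `PASS` or `SUFFCLIP` enter the
analyses; `FAIL` reads are dropped by `filter_qc()`. References are a
`Biostrings::DNAStringSet` genome plus a transcript annotation tibble
(read/written as a GTF-like text format with 1-based inclusive coordinates
on disk and 0-based half-open coordinates in memory).

## Differential adenylation

`differential_adenylation()` compares tail-length distributions per
transcript between conditions with a two-sided Mann–Whitney rank-sum test.
Per-read tail lengths are heavily right-skewed and replicate reads within a
condition are pooled, so a rank test on the pooled reads is the natural
choice; the test is equivalent to the signed-rank family of nonparametric
location tests used for tail data, applied in its two-independent-samples
form because the two conditions are measured in different animals, not
paired within one.

* **Exact path.** When the smaller group has at most 8 reads and there are
  no ties, the exact null distribution of the U statistic (`pwilcox`) is
  used; the two-sided p-value is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
* **Normal path.** Otherwise a normal approximation with tie-corrected
  variance and a 0.5 continuity correction is used, matching
  `wilcox.test(correct = TRUE)`.

A transcript is tested only with **at least 10 reads in each condition**
(inclusive); transcripts below the threshold are reported in a warning and
excluded. Significance requires **both** BH-adjusted `p_adj < 0.05` and an
absolute median tail-length difference **strictly greater than 5 nt** — the
effect-size gate keeps trivially small but well-powered shifts out of the
significant set. Cohen's d accompanies each test and is binned
lower-inclusively at 0.2 / 0.5 / 0.8 (negligible / small / medium / large).

## Differential expression

`differential_expression()` collapses reads to a transcript × sample count
matrix and runs a deliberately simple negative-binomial Wald test
(`nb_wald_test()`):

1. size factors by the median-of-ratios method (the geometric-mean
   reference used by DESeq-style normalization; genes with any zero are
   excluded from the reference);
2. a single pooled moment estimate of dispersion per gene,
   `alpha = max(1e-8, (s^2 - mu_bar) / mu_bar^2)`, from within-condition
   variances of normalized counts;
3. `log2_fc = log2((mu_stim + 0.5) / (mu_ctrl + 0.5))` with a 0.5
   pseudocount, a delta-method standard error, a Wald z statistic, and BH
   adjustment.

This is intentionally a transparent, oracle-testable approximation of the
shrinkage-based NB GLM machinery of dedicated packages; the test suite
checks its size factors against `DESeq2::estimateSizeFactorsForMatrix()`
and its type-I error by simulation. It is not meant to replace DESeq2 for
real data with few replicates and strong outliers.

## PAS calling and differential usage

`cluster_read_ends()` groups QC-passing read 3' ends per gene by
single-linkage with a **24 nt** gap (ends at most 24 nt apart join one
cluster), keeps clusters with **>= 3** supporting reads, and anchors each
cluster at its modal end position, breaking ties toward the 3'-most
position in mRNA orientation (nanopore 3' ends jitter symmetrically around
the true cleavage site, so the mode is the best point estimate).
`assign_pas_features()` labels each anchor by annotation precedence: 3'UTR
> exon > intron > unassigned.

`differential_pas_usage()` tests each PAS of every multi-PAS gene with a
two-sided Fisher exact test of the 2×2 table *(this PAS vs the gene's other
PASs) × (control vs stimulated)* — read counts at one site are naturally
conditioned on the gene's total, so the hypergeometric exact test applies
directly. PASs with BH-adjusted `p <= 0.1` are flagged `differential` (a
more permissive threshold, since usage shifts split power across sites).
`log2_shift` is the size-factor-normalized, 0.5-pseudocounted
stimulated/control support ratio. `hexamer_enrichment()` profiles AATAAA
and ATTAAA occurrences in the window upstream of each anchor (mRNA sense on
both strands); a functional PAS shows the canonical hexamer concentrated
near offset −20.

## CPE scanning

`read_meme_motifs()` parses MEME minimal format; `build_log_odds()` forms
`log2(((p + 0.01 * bg) / 1.01) / bg)` position weight matrices (pseudocount
0.01 weighted by background). Scanning is FIMO-style: scores are rounded to
an integer lattice (scale 1000) and the exact null score distribution is
built by positional convolution over the background, giving exact p-values
for every achievable score. Sites with `p <= 1e-4` are reported; windows
containing `N` never match. `annotate_cpe()` flags transcripts whose 3'UTR
contains a motif hit. The DP is validated in the test suite against brute
force enumeration of all `4^W` words.

## Semi-templated tails

Some apparent poly(A) tails are partly genome-templated: the transcript's
terminal 3'UTR sequence is A/T-rich enough that basecalling absorbs it into
the tail. `call_semitemplated()` inspects the **60 nt** window ending at
each candidate 3' end (annotated 3'UTR terminus and every called PAS) and
flags the window when either rule holds:

* **Rule 1:** A/T fraction strictly greater than 0.60;
* **Rule 2:** a run of >= 13 consecutive A/T nucleotides *and* the
  window's final 3 nt all A/T (a long A-stretch only produces tail
  read-through when it reaches the cleavage site).

Rules are OR-reduced per transcript over its windows, and a transcript is
**called** only with read support: >= 10 QC-passing reads and >= 3 tails
containing at least one non-adenosine (decoration is what distinguishes a
sequenced tail from a homopolymer artifact). All intermediate set sizes are
kept in the `"set_sizes"` attribute.

## Mechanism discrimination

`classify_mechanism()` places each gene on a two-axis map — expression
state (up / down / unchanged) against tail state (elongated / shortened /
unchanged) — and labels the quadrants:

| expression | tail      | label                                   |
|------------|-----------|------------------------------------------|
| up         | elongated | `transcriptional_induction`              |
| unchanged  | elongated | `cytoplasmic_polyadenylation_candidate`  |
| down       | shortened | `deadenylation_decay`                    |
| unchanged or up | shortened | `translation_deadenylation_like`   |
| otherwise  |           | `stable`                                 |

The logic: newly transcribed mRNAs carry long nascent tails, so an
abundance increase with tail elongation is parsimoniously explained by
transcription; elongation without an abundance change requires cytoplasmic
re-adenylation; coupled shortening and decay reflects
deadenylation-triggered turnover. `correlate_expression_adenylation()`
quantifies the first effect as a Pearson correlation between `log2_fc` and
the mean tail change among significant tail changers.

## The synthetic-data generator

`simulate_dataset()` is both the test harness and the package's worked
dataset. Defaults are the study conditions and are never tuned to analysis
outcomes:

* 500 single-exon genes, one contig each, 400 nt transcripts with 200 nt
  3'UTRs; 4 replicates per condition; NB counts with mean 12.5
  reads/gene/sample and dispersion 0.05 (~50 reads per transcript per
  condition, a realistic DRS depth);
* lognormal tails, baseline median 60 nt, `sdlog` 0.35 (nanopore tail
  medians cluster near 60 nt with right skew);
* mechanisms drawn per gene at fractions 0.70 null / 0.10 induction
  (4-fold, +40 nt) / 0.10 cytoplasmic polyadenylation (+40 nt) / 0.10
  deadenylation-decay (4-fold down, −40 nt);
* tail decoration: each tail position is a non-adenosine with probability
  0.002, biased G ≥ C ≥ U (0.5/0.3/0.2), matching observed guanosine-rich
  tail modifications;
* 30% of genes carry a second, proximal PAS 150 nt upstream with usage
  0.3 → 0.6 across conditions; AATAAA is planted 20 nt upstream of every
  PAS;
* 10% of genes are semi-templated: an 18 nt genomic suffix
  (`TG` + 16×`A`) is fused into every read's apparent tail, and reads end
  18 nt upstream of the annotated terminus; background 3'UTR termini are
  rejection-sampled to fail both rules, so ground truth is exact;
* read 3' ends jitter around their PAS with SD 2 nt; QC tags are drawn at
  0.90/0.08/0.02 (PASS/SUFFCLIP/FAIL).

Determinism is per-gene: every gene derives an independent sub-seed from a
stable string hash of (seed, gene id), so results are byte-identical for a
given seed and unchanged for existing genes when `n_genes` grows. The
generator's scope is deliberately limited — single-exon transcripts, no
basecalling error model beyond tail decoration and end jitter, no
batch/animal random effects — it is a ground-truthed test bed, not a
sequencing simulator.

## Numerical and reproducibility choices

* All exact tests (rank-sum exact path, Fisher, PWM p-values) are computed
  in closed form or by exact DP — no Monte Carlo — and are compared against
  independent brute-force oracles in the test suite.
* BH adjustment is the standard step-up procedure
  (`p * n / rank`, cumulative minimum from the largest p).
* All randomness flows from the single `seed` in `sim_config()`; the
  pipeline itself is deterministic, and `write_report()` output is
  byte-identical across runs with the same configuration.

One testing choice is worth recording: the acceptance test for PAS-usage
recovery simulates at `baseline_mean_expression = 25` (~100 reads per
condition) because the Fisher test on a 0.3 → 0.6 usage shift is
power-limited at the default depth; the default itself is unchanged, and
all other criteria run at the defaults above.

## Limitations

The NB Wald test has no dispersion shrinkage and will be anti-conservative
for very low replicate counts on real data; the PAS caller assumes 3' ends
are observed at read resolution (no internal priming model); the
semi-templated rules are sequence-only heuristics and inherit their fixed
thresholds; and the mechanism map is a labeling of marginal test outcomes,
not a joint model with error propagation between the two axes.
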