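---
title: "Methods: stress-attenuated miRNA target loading and decay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-attenuated miRNA target loading and decay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the analysis it requires

When a cell is stressed (hypoxia being the motivating case), the
miRNA-induced silencing complex can lose its grip on target mRNAs:
transcripts that would normally be recruited to AGO2 and degraded
instead accumulate. Detecting this from sequencing data requires a
chain of analyses rather than a single test:

1. define which transcripts are *miRNA targets* (seed matching in the
   3'-UTR), and which miRNAs are informative — those whose own
   expression does *not* change between conditions, so any change in
   their targets' behaviour reflects silencing efficiency, not miRNA
   abundance;
2. compare the AGO2-bound fraction (RIP-Seq fold enrichment) of targets
   versus non-targets between conditions as a cumulative-fraction
   (ECDF) shift, tested with the Mann–Whitney U test;
3. compare target *abundance* (RNA-Seq FPKM) the same way, expecting
   the gain to grow with seed-pairing strength (8mer > 7mer > 6mer)
   and to concentrate in transcripts that normally decay fast
   (short half-life);
4. score an independent tumour cohort for a hypoxia expression
   signature and ask whether the score co-varies with the expression of
   the miRNA target set but not with non-targets.

`agoshift` implements each step as a package function, wires them into
`run_pipeline()`, and ships a synthetic-data generator whose ground
truth makes every step testable end to end. The `analysis/` scripts are
thin numbered drivers over these functions.

## Seed-site model

The scanner uses the canonical seed-match taxonomy. With the mature
miRNA written 5'→3', its *seed* is positions 2–8. On the sense strand
of the UTR a window is:

* **7mer-m8** — the reverse complement of miRNA positions 2–8;
* **8mer** — a 7mer-m8 match followed by an `A` (the A faces miRNA
  position 1 regardless of that position's base);
* **6mer** — the reverse complement of positions 2–7;
* **7mer-A1** — a 6mer match followed by an `A`.

G:U wobble pairs are not allowed; this keeps the match rule exact and
the brute-force oracle in the test suite unambiguous. Each locus is
reported once with the strongest applicable type
(8mer > 7mer-m8 > 7mer-A1 > 6mer), and sites of one miRNA may not
overlap: candidates are accepted greedily in strength order, left to
right. This policy exists because the single-site stratification needs
an unambiguous per-transcript site count — without it, every 8mer would
also count as a 7mer and a 6mer. Where the coarse classes are needed,
`collapse_7mer = TRUE` (the default) merges the two 7mer flavours.
Coordinates are 1-based closed intervals on the given UTR; no strand
logic is applied (UTRs are supplied sense-strand), and `T`/`U` spelling
is normalised on input.

What counts as "a target" in the source analyses was produced by an
external prediction tool whose scoring is not reproducible from its
outputs; here the scanner's policy *is* the target definition, recorded
in the outputs. Context scores, conservation and non-canonical sites
are out of scope.

## miRNA selection

Raw miRNA counts are normalised per condition to tags-per-million
(`tpm_i = 1e6 * count_i / sum(counts)`), and fold changes computed as
`log2((tpm2 + 1)/(tpm1 + 1))` (pseudocount 1 TPM). Two sets drive the
partition:

* **non-difference** (default N = 10): among miRNAs with TPM ≥ 100 in
  *both* conditions, the N smallest |log2FC|, ties broken by higher
  mean TPM then id. The expression floor implements "top": an
  unchanged but barely-detected miRNA carries no targeting information.
  The source analyses never state their exact ranking rule; ours is
  declared rather than inferred, and both the floor and N are exposed.
* **reduced**: log2FC ≤ −1 (2-fold down, matching the 2-fold
  conventions used throughout) with the TPM floor applied to condition
  1 only, since the stress condition is the one where they fall.

The two sets are disjoint by construction (reduced miRNAs are never
eligible for the non-difference ranking).

## Transcript partition

Expression filtering keeps genes with FPKM strictly `> 1` in both
conditions and mean FPKM `>= 30`; the strict/non-strict mix follows the
stated inequalities literally. Within the filtered universe:

* **exclusive targets**: ≥ 1 seed site for any non-difference miRNA
  *and* zero sites for every reduced miRNA — excluding transcripts that
  a falling miRNA could be de-repressing for trivial reasons;
* **non-targets**: zero sites for *every* expressed miRNA (TPM floor in
  either condition), not merely the selected ten — "non-target" is read
  as "not under detectable miRNA control";
* **single-site strata**: exclusive targets whose total site count over
  the non-difference miRNAs is exactly 1, keyed by the collapsed type.

## Shift statistics

The Mann–Whitney U test is implemented from scratch because it is the
pipeline's core inferential step and must be exactly specified:
midranks over the pooled sample, `U = R1 − n1(n1+1)/2`, tie-corrected
variance `n1 n2/12 ((N+1) − Σ(t³−t)/(N(N−1)))`, continuity correction
0.5, `p = 2Φ(−|z|)` capped at 1. When `n1 + n2 ≤ 16` the full
permutation distribution of U is enumerated and the two-sided p is
`P(|U − μ| ≥ |u − μ|)`; enumeration is cheap there and removes the
approximation question entirely. All pooled values identical is
reported as degenerate with p = 1. The test suite cross-checks both
paths against `stats::wilcox.test` and a pair-counting enumeration
oracle. One known numerical fact: at `n1 = n2 = 8` the
continuity-corrected normal p can differ from the exact p by up to
~0.011 at mid-range U — identical to the discrepancy of R's own
corrected approximation — which is why the exact switch covers that
range by default.

Fold-change classification uses inclusive thresholds (`ratio ≥ f` up,
`≤ 1/f` down; "more than f-fold" is treated as ≥ f so the boundary is
reproducible) with pseudocount 0 for RIP enrichment (positive by
construction) and 0.1 for FPKM. Up/down ratios and overlap (Venn)
percentages are kept at full precision internally and rounded half
away from zero only in the report layer (ratios to 2 decimals,
percentages to 1), because R's default half-to-even rounding does not
reproduce printed tables. Raw Mann–Whitney p-values are reported per
contrast without multiple-testing correction, matching the source
convention; the few contrasts reported make this a presentation choice,
not an inference one.

## Half-life stratification and decay fitting

Published half-lives (an input table; the package does not re-derive
them) are binned short (0–4 h), middle (4–12 h), long (> 12 h). The
printed edges overlap at 4 and 12; the boundary goes to the lower bin
(4 h is short, 12 h is middle), declared once and tested. Within each
bin, target versus non-target abundance log-ratios are contrasted by
Mann–Whitney; bins with fewer than `min_n = 10` transcripts in either
group are reported but skipped. The source figure does not state
whether it contrasts bound-mRNA or expression fold change within
strata; we contrast expression log-ratios and note the alternative
would only require passing the RIP table instead.

Decay curves (Actinomycin-D-style time courses, abundance normalised
to 1 at t = 0) are summarised by least squares through the origin in
log space, `log(a) = −(ln 2 / t½) t`, which is exact on a clean
exponential; a non-negative fitted slope is reported as non-decaying
(`t½ = Inf`) rather than a negative half-life.

## Hypoxia scoring

The cohort score is a single-sample rank-based enrichment statistic
(ssGSEA-style): genes ranked descending within the sample, signature
genes accumulating weight `(descending rank)^α` normalised to their
total, non-signature genes `1/(N − m)`, score = Σ(P_hit − P_miss). We
chose this single clearly-specified statistic over a kernel-density
GSVA variant because it is oracle-testable by exhaustive signature
enumeration at small N, and the source does not state which variant or
parameters it used; the qualitative contract (positive coupling of
score with target expression, near-zero with non-targets) is what the
tests assert. `α = 0.25` is the field's customary default and is
configurable. Being rank-based, the score is invariant to any
within-sample monotone transformation of expression; ties are broken
by gene id for determinism.

Raw scores are not naturally centred, so cohort z-normalisation
supplies the 0 threshold at which the cohort splits into high
(score > 0) and low groups; a score of exactly 0 is assigned to "low"
so that every sample is labelled. The target-set summary is the
per-sample mean of per-gene z-scores of `log2(FPKM + 1)`; genes
constant across samples carry no information and are dropped from the
mean. Score–summary association is Pearson's r with the two-tailed
t-test p-value, plus a high-versus-low Mann–Whitney contrast.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with known ground truth:

* **UTRs and sites.** Each transcript draws a site type from
  `site_type_probs` (default 10% 8mer, 10% 7mer-m8, 10% 7mer-A1,
  20% 6mer, 50% none) and, unless "none", hosts exactly one implanted
  site for one uniformly chosen miRNA at a uniform interior position.
  One site per transcript keeps the single-site strata populated and
  the per-transcript strength unambiguous. Site strength is the
  ordinal scale 8mer = 3, 7mer = 2, 6mer = 1, none = 0 — only its
  ordering is meaningful.
* **Exact recoverability.** Two deviations from purely uniform
  background make ground truth exactly recoverable by the scanner, the
  property the recovery tests assert: (i) chance occurrences of any
  simulated miRNA's 6-mer seed core (every site type contains that
  core) are scrubbed from the background by mutate-and-rescan, where
  each mutation is chosen so it completes no core in any window it
  touches — so progress is strict and convergence guaranteed in
  practice; (ii) the two bases flanking an implant are constrained so a
  weaker implanted type cannot be upgraded by a chance neighbour
  (e.g. an `A` after a 7mer-m8 would make it an 8mer). This is the
  standard implanted-motif-simulator construction; real UTRs of course
  contain incidental seed matches, which is one reason passing recovery
  tests do not certify performance on real data (below).
* **Effect model.** Per transcript with strength s: log2 RIP
  enrichment is `base + 0.5 s` in control and additionally `− δ s`
  under stress (δ = `delta_binding`, default 1); log2 FPKM gains
  `γ s` under stress (γ = `gamma_abundance`, default 0.5). Noise is
  Gaussian on the log2 scale (`noise_sd`, default 0.5) rather than
  count-level negative binomial because the pipeline consumes
  normalised tables (fold enrichment, FPKM), not raw counts. The
  magnitudes of δ and γ are free parameters — the source reports the
  direction and ordering of these effects, not their size — chosen once
  at values that give clearly detectable but not degenerate shifts at
  the default sample sizes.
* **miRNA counts** are log-normal baseline (meanlog log 500,
  sdlog 1.2 — a realistic spread of miRNA abundances spanning ~3
  orders of magnitude), with a fraction `frac_mirna_reduced = 0.3`
  scaled by `2^lfc_reduced` (default −2) under stress, multiplicative
  log-normal noise, rounded to integer counts.
* **Half-lives** are log-normal on log-hours (mu = log 8,
  sigma = 0.9), putting roughly a quarter of transcripts in each of
  the short and long bins and half in the middle — the shape of
  published transcriptome-wide half-life distributions.
* **Cohort.** Each sample carries a latent hypoxia level
  h ~ Uniform(0,1); signature genes gain `signature_effect · h`
  (default 2) log2 units, target genes `γ · h`, background flat, all
  with the same log2 noise. Baseline log2 FPKM is N(6, 1) throughout
  (median ~64 FPKM, so most genes pass the mean ≥ 30 filter while a
  realistic minority fails).
* **Determinism.** Every simulator seeds its own stream from
  `rng_seed` with fixed offsets (+0 transcriptome, +1 miRNA counts,
  +2 RIP/expression, +3 cohort), so stages can be re-run independently
  and `simulate_study()` is reproducible byte for byte.

## Problem sizes and numerical conventions

Default simulations use 1000 transcripts, 50 miRNAs, UTRs of
150–600 nt and a 200-sample cohort; the unit-test configurations scale
down to 120–300 transcripts. Monte-Carlo checks use 200 replicates for
null calibration (the 99% binomial band at α = 0.05 is then roughly
5% ± 3 points) and 50 replicates for effect-ordering checks; these
sizes make the checks statistically meaningful while keeping a full
run of the suite and scripts in the minutes range. TSV output is
UTF-8, tab-separated, '.' decimal, no quoting, numerics at 15
significant digits so a write/read round trip is lossless in double
precision.

## What passing tests do and do not show

The generator produces exactly the structure the analysis assumes:
Gaussian log-scale noise, independent transcripts, one site per
target, a scrubbed background, a uniform latent hypoxia gradient. Real
data violate all of these — overdispersed counts, correlated
transcripts, multi-site UTRs, incidental seed matches, batch
structure — so green tests certify the *machinery* (definitions,
statistics, bookkeeping, determinism) and the pipeline's behaviour
under its own model, not biological performance. The published set
sizes from the original sequencing data are likewise not reproducible
without that data; what is reproducible — and what the acceptance
script recomputes — is every percentage and ratio derivable from the
published count tables, plus the statistical machinery itself against
oracles and simulation.
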