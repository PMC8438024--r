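# agoshift

Downstream analysis of AGO2 RIP-Seq / RNA-Seq / miRNA-Seq experiments
asking whether a stress condition (e.g. hypoxia) attenuates
miRNA-targeted mRNA loading to AGO2 and thereby inhibits target decay.
Intended for computational biologists who have per-transcript AGO2
fold-enrichment tables, FPKM matrices and miRNA counts for two
conditions and want the full chain from seed-site calling to
cohort-level signature scoring — plus a synthetic-data generator with
recoverable ground truth so every step can be validated end to end.

## What it computes

* **Seed-site scanning** in 3'-UTRs with the canonical taxonomy: a UTR
  window is a 7mer-m8 site if it equals the reverse complement of
  miRNA positions 2–8; 8mer adds a downstream `A` (facing position 1);
  6mer is the reverse complement of positions 2–7; 7mer-A1 adds the
  `A` to a 6mer. No G:U wobble. Each locus is reported once with the
  strongest type (8mer > 7mer-m8 > 7mer-A1 > 6mer), greedily
  non-overlapping per miRNA.
* **miRNA selection**: TPM normalisation (`tpm_i = 10^6 c_i / Σc`),
  pseudocounted log2 fold changes, the top-N *non-difference* set
  (smallest |log2FC| among well-expressed miRNAs) and the
  *stress-reduced* set (log2FC ≤ −1).
* **Transcript partition** after FPKM filters (> 1 in both samples,
  mean ≥ 30): exclusive targets (sites only for non-difference
  miRNAs), non-targets (no sites for any expressed miRNA), and
  single-site 6mer/7mer/8mer strata.
* **Cumulative-fraction shift statistics**: ECDFs and a from-scratch
  two-sided Mann–Whitney U test — midranks,
  `U = R₁ − n₁(n₁+1)/2`, tie-corrected variance
  `n₁n₂/12 [(N+1) − Σ(t³−t)/(N(N−1))]`, continuity correction 0.5,
  with exact enumeration of the permutation distribution when
  `n₁+n₂ ≤ 16`. Plus fold-change class counts/ratios, Venn overlap
  percentages, and Pearson correlation with the two-tailed t p-value.
* **Half-life stratification** (short 0–4 h, middle 4–12 h,
  long > 12 h) with per-stratum shift tests, and exponential
  decay-curve fitting `log a = −(ln2/t½) t` through the origin.
* **Hypoxia scoring**: a single-sample rank-based signature enrichment
  score (ssGSEA-style, weight exponent α = 0.25), cohort
  z-normalisation, a high/low split at score 0, and correlation of the
  score with target-set expression summaries.

## Worked example

The `analysis/` directory holds the numbered drivers; running them in
order reproduces the whole study on synthetic data:

```sh
Rscript analysis/01_simulate_data.R     # inputs -> results/data/
Rscript analysis/02_scan_and_select.R   # sites, selection, partition
Rscript analysis/03_shift_analysis.R    # ECDF shifts, strata, decay
Rscript analysis/04_cohort_scoring.R    # cohort hypoxia scores
```

With the shipped defaults (1000 transcripts, 50 miRNAs, binding
attenuation δ = 1 and abundance gain γ = 0.5 log2 units per unit seed
strength, seed 101) the drivers print:

```
After expression filtering ( 905 transcripts ): 91 exclusive targets, 441 non-targets.
Single-site strata: 6mer 36, 7mer 32, 8mer 23

RIP loading, targets vs non-targets: median shift -1.9 log2 units, MWU p = 1.19e-41
Abundance, targets vs non-targets: median shift 0.87 , MWU p = 2.9e-19
Single-site strata median abundance shifts:
  6mer : 0.56 ( p = 9.71e-05 )
  7mer : 0.97 ( p = 2.55e-10 )
  8mer : 1.34 ( p = 3.34e-11 )

Scored 200 samples: 102 high-hypoxia (score > 0), 98 low-hypoxia.
targets (n = 91 genes): Pearson r = 0.920, p = 1e-82
background (n = 441 genes): Pearson r = 0.052, p = 0.466
```

Read: under stress the targets' AGO2 loading distribution is
left-shifted (−1.9 log2 units at the median) while their abundance is
right-shifted, the abundance gain orders by seed strength
(8mer > 7mer > 6mer), and in the cohort the hypoxia score tracks
target expression (r = 0.92) but not the non-target background
(r ≈ 0.05). The same end-to-end run is available programmatically:

```r
library(agoshift)
res <- run_pipeline(pipeline_config(out_dir = "results/pipeline"))
res$shift$tests          # every contrast: n1, n2, U, z, p, median shift
```

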