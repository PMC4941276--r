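---
title: "Methods: differential methylation, enhancer enrichment and target linking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation, enhancer enrichment and target linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflamethyl)
```

## The analysis

Chronically inflamed tissue acquires a characteristic epigenome: broad loss
of DNA methylation punctuated by focal gains at distal regulatory elements.
`inflamethyl` implements the computational pipeline for characterising that
state from beta-value methylation arrays and the surrounding regulatory
genomics data:

1. **Differential methylation.** Per-probe comparison of case and control
   beta values, FDR correction, and calling with an effect-size filter.
2. **Permutation enrichment.** Whether the called probes concentrate in (or
   avoid) a set of genomic features — histone-mark peaks, DNase
   hypersensitive sites (DHS), enhancer catalogues — relative to the array
   background.
3. **Enhancer–target linking.** Putative enhancers (DHS without H3K4me3),
   restricted to those containing hypermethylated probes, linked to target
   gene promoters by correlating DNase signal across many cell lines.
4. **Cross-cohort overlap.** Directional comparison of differential probe
   sets between two cohorts with the hypergeometric test.
5. **Context statistics.** RRBS methylation partitioned by
   chromatin-looping-factor binding peaks with Kolmogorov–Smirnov testing,
   MS-HRM categorical analysis with Fisher's exact test, Spearman
   methylation–expression correlation, and Mann–Whitney group comparisons.

Every stage takes plain data frames and returns tibbles, so stages compose
with the pipe; `run_pipeline()` chains them end to end.

## Models and conventions

### Coordinates and interval algebra

All internal coordinates are 0-based half-open (the BED convention); array
manifests, which are conventionally 1-based, are converted on read
(`read_manifest(path, base = 1)`). A CpG probe is a single base — the
interrogated cytosine — and overlap with a peak means that base falls
inside the half-open interval. The probe body is deliberately not modelled:
counting overlap between *the CpG* and a peak is the cleanest reading of
how probe/peak overlap is defined in this field, and the 50-mer alternative
would only blur boundaries by ±50 bp.

Nearest-feature distance counts the bases strictly between a position and
an interval's covered bases, so position 300 is 100 bp from `[100, 200)`.
CpG-island context follows the standard Illumina bands: island (inside),
shore (≤ 2 kb), shelf (2–4 kb), open sea (> 4 kb; only the open-sea bound
is field-canonical, the shore/shelf split is the standard convention that
fills in the rest). Gene context applies the precedence
promoter > exon > intron > intergenic, with the promoter window ± 2.5 kb
around the TSS. Strand is used only to place the TSS.

Interval queries run on IRanges; unit and acceptance tests cross-check them
against naive all-pairs scans.

### Per-probe test

Beta values in a two-group comparison are tested with a two-sided Welch
two-sample *t*-test, vectorised over probes for array-scale speed and
cross-checked against `stats::t.test()`. Welch on beta values is the
simplest defensible default for moderately sized cohorts; the choice is
isolated behind `test_probe()` and a `test = "wilcoxon"` variant is a
one-argument swap. Degenerate zero-variance probes follow a documented
convention — both groups constant and equal gives p = 1, constant and
different gives p = 0 — because synthetic fixtures (and occasionally
saturated probes) hit these cases. Probes with fewer than two observed
values in either group are excluded and counted.

FDR control is Benjamini–Hochberg in one batch across all tested probes.
Calls use strict inequalities: hyper iff q < 0.05 **and** Δβ > 0.15, hypo
iff q < 0.05 and Δβ < −0.15. Both thresholds are the field-standard values
for this analysis and are exposed in `meth_thresholds()`.

### Permutation enrichment

The null for "do my probes sit in these peaks more than expected?" is
built by drawing, 1,000 times, an equal-sized probe set uniformly without
replacement from the full array manifest and counting overlaps. The
background is the whole array — no matching on CGI content or chromosome —
because the question is posed against the array's own distribution.
Z-scores use the sample standard deviation of the null; empirical p-values
use the add-one estimator `(1 + #{null ≥ obs}) / (n_perm + 1)` so they are
never zero. A direction (enriched/depleted) is called when the empirical p
is below 0.05; the null for each (probe set × feature set) cell is seeded
as `seed + cell index`, making the report bit-reproducible and
embarrassingly parallel in principle.

### Enhancer linking

Putative enhancers are DHS with zero base-pair overlap with any H3K4me3
peak. Enhancers containing at least one hypermethylated probe are anchors.
For each anchor, every signal-matrix site on the same chromosome whose
midpoint lies within ± 500 kb is a candidate; the Pearson correlation of
DNase signal across cell lines is computed and links with r² ≥ 0.7 are
emitted, sorted by descending r². Distance is midpoint-to-midpoint — edges
are not well defined for the question "what surrounds this enhancer", and
midpoints make the window symmetric and configuration trivial. A target
is annotated with a gene when its midpoint lies within ± 2.5 kb of a TSS
(nearest TSS wins; exact ties break lexicographically on gene id, so runs
are deterministic). Correlation is computed on raw signal by default with
a `log_signal` option, since DNase signal is heavy-tailed and the right
transform is data-dependent. An anchor is matched to the signal-matrix
site it overlaps most, and an anchor overlapping no site is an error: an
enhancer called from DHS should itself be a DHS.

### Cross-cohort overlap

The universe is the intersection of probes *tested* in both cohorts, not
the full array — a probe absent from one cohort's data cannot overlap
anything, and conditioning on availability is what the reported "with
available data" set sizes imply. Each of the four direction pairs
(A-hyper × B-hyper, …) reports the overlap `k`, the proportion `k / nA`,
and the one-sided upper-tail hypergeometric p computed through
`phyper(..., lower.tail = FALSE, log.p)` so tails of order 1e-200 survive.
No correction is applied across the four cells; raw hypergeometric
probabilities are the convention for this display.

### Context statistics

RRBS records are filtered to ≥ 5× coverage (inclusive), partitioned by
binding-peak overlap, and the two beta distributions compared with the
two-sample Kolmogorov–Smirnov test using the asymptotic p-value — the
intended regime is 10⁵–10⁶ CpGs per arm, where an exact small-sample mode
would be pointless. The MS-HRM analysis dichotomises the four melting bins
into fully-unmethylated (0–5%) versus any methylation, because a 2×2 table
is the only version whose counts are completely determined by the reported
group sizes; the published healthy-group counts are internally
inconsistent at the margin (41/44 unmethylated alongside four samples in
the 6–10% bin) and the table uses 41 vs 3 to respect n = 44 — documented
here rather than silently resolved. Bin midpoints are bin-edge means
(0–5% → 2.5%). Spearman correlation uses mid-ranks; Mann–Whitney uses
exact enumeration when `n·m ≤ 400` without ties, otherwise the
tie-corrected normal approximation.

## The synthetic study generator

`gen_synthetic_study()` produces every input the pipeline consumes, with
planted ground truth, so the whole analysis is testable at desk scale with
no downloads. Its defaults *are* the study conditions:

| parameter | default | emulates |
|---|---|---|
| `n_case` / `n_control` | 19 / 23 | the inflamed/healthy cohort sizes |
| `n_probes`, `genome_length` | 10,000 on 20 Mb | a 450K-like manifest, scaled down |
| `effect_delta` | 0.25 | planted Δβ, comfortably above the 0.15 call threshold |
| `beta_concentration` | 50 | per-sample Beta noise (sd ≈ 0.06 at β = 0.2) |
| `frac_hyper` / `frac_hypo` | 0.05 / 0.05 | 500 + 500 planted probes |
| `feature_base_rate`, `enrichment_fold` | 0.10, 5× | peak sets covering 10% of probes, 5-fold over-representation among planted hyper probes |
| `n_planted_links`, `n_decoy_dhs`, `n_cell_lines`, `link_r` | 50, 500, 100, 0.9 | enhancer–promoter pairs sharing latent DNase activity among independent decoys |
| `exclusivity_strength` | 1 | full methylation suppression inside binding peaks |

Design choices worth knowing:

* **Planted baselines are mode-matched.** Unplanted probes draw a bimodal
  baseline (the classic two-peaked array shape). Planted hyper probes draw
  their baseline from the *unmethylated* mode and planted hypo probes from
  the *methylated* mode, so the planted ± 0.25 effect is realised without
  truncation at the [0, 1] boundary. This also mirrors the biology: focal
  methylation gain happens at normally-unmethylated regulatory elements.
  Means that would still leave [0.005, 0.995] are clipped and counted.
* **One synthetic chromosome.** The interval logic is
  chromosome-agnostic, and a single chromosome keeps fixtures small and
  layouts easy to reason about.
* **Signal construction.** A planted pair shares a latent per-cell-line
  activity `a ~ N(0, 1)`; each member observes `10 + 2a + ε` with
  `ε ~ N(0, σ²)` and `σ² = 4(1 − r)/r`, giving true correlation `r` (0.9
  by default; Pearson correlation is invariant to the affine scale).
  Decoys get independent signal. Anchors are centred on planted
  hypermethylated probes, so the DHS/H3K4me3/linking stages connect to the
  differential-calling stage exactly as they do on real data.
* **RRBS.** Outside peaks, beta is a 50/50 high/low Beta mixture; inside
  peaks, a near-zero mode replaces the mixture with probability
  `exclusivity_strength`, so the mutual-exclusivity effect dials smoothly
  from absent to complete. One fifth of records have coverage below 5× to
  exercise the filter.
* **Second cohort.** For the cross-cohort stage, 60% of the primary
  cohort's planted probes are re-planted in the same direction and the
  remainder refilled from unplanted probes, so same-direction overlap is
  strong and cross-direction overlap is empty by construction.

What the generator does **not** emulate — and hence what green tests do
not show about real data: probe-level artefacts (cross-hybridisation,
SNPs under probes), batch and cell-composition effects, spatially
correlated methylation along the chromosome, non-Beta heteroscedasticity,
and quantile-normalisation questions in the DNase signal. Passing the
recovery criteria demonstrates that the *machinery* is correct and
calibrated, not that real cohorts will separate this cleanly.

## Numerical choices

* Degenerate permutation nulls (zero sd) return `z = NA`, direction
  `none`, and a flag, with the empirical p still computed.
* `hypergeom_upper()` and the KS/Fisher/Wilcoxon kernels delegate to the
  corresponding `stats` routines; tests verify them against exhaustive
  enumeration (complete hypergeometric lattice for N ≤ 12, all 2×2 tables
  with total ≤ 20) and hand formulas (BH step-up).
* Nearest-feature ties (equidistant intervals) cannot change the reported
  distance; tie-breaking only matters for gene assignment, where it is
  lexicographic and therefore deterministic.
* All randomness flows through explicit seeds; generators use disjoint
  streams derived from the master seed (`seed + 1`, `seed + 2`, …), and
  repeated generation is byte-identical on disk.

## Problem sizes used in the checks

The packaged checks run the generator at 10,000 probes with 20/20 samples
(null FDR and recovery), 200 null enrichment runs and 20 planted-enrichment
generations at 1,000 permutations each, the 50-pair/500-decoy/100-cell-line
linking problem, and 40,000 RRBS records per exclusivity level (≥ 5,000
per arm after filtering). These sizes were chosen so each property is
measured with comfortable statistical margin while the whole suite stays
interactive on a laptop.

## Known limitations

* The per-probe test is not moderated (no empirical-Bayes variance
  shrinkage); at very small n a limma-style moderated test would be more
  powerful. The package targets the cohort sizes above, where Welch is
  adequate.
* Putative-enhancer calling treats any H3K4me3 overlap as disqualifying,
  with no signal-strength weighting.
* The R×C (four-bin) Fisher–Freeman–Halton variant of the MS-HRM analysis
  is out of scope; the 2×2 dichotomisation is the implemented contract.
* Real-data ingestion expects pre-normalised beta matrices; no array
  normalisation, background correction or batch correction is performed.
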