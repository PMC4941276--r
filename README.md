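# inflamethyl

Epigenome-wide analysis of DNA methylation in chronically inflamed tissue,
for researchers comparing beta-value methylation arrays between a diseased
and a healthy cohort and asking where the differential CpGs land in the
regulatory genome.

Chronic inflammation leaves a characteristic methylome: widespread loss of
methylation with focal gains concentrated at distal regulatory elements
(enhancers) rather than promoters — a pre-neoplastic configuration also
seen in tumors arising at the same sites. `inflamethyl` implements the
computational pipeline for characterising that state:

* **Differential methylation** — per-probe Welch *t*-test on beta values,
  Benjamini–Hochberg FDR, calls at *q* < 0.05 and |Δβ| > 0.15 where
  Δβ = mean β(case) − mean β(control).
* **Permutation enrichment** — observed overlap of a differential probe
  set with a feature set (ChIP-seq peaks, DHS, enhancer catalogues)
  against 1,000 equal-sized probe sets resampled from the array
  background; Z = (obs − μ₀)/σ₀ with add-one empirical p.
* **Enhancer→target linking** — putative enhancers are DHS without
  H3K4me3; hypermethylated enhancers are linked to promoters (±2.5 kb of
  a TSS) by Pearson correlation of DNase signal across cell lines, within
  ±500 kb and at r² ≥ 0.7.
* **Cross-cohort overlap** — the four directional hyper/hypo cell
  overlaps between two cohorts with upper-tail hypergeometric
  probabilities over the jointly-tested probe universe.
* **Context statistics** — coverage-filtered (≥5×) RRBS methylation
  partitioned by CTCF/cohesin binding peaks with two-sample
  Kolmogorov–Smirnov tests; MS-HRM category tables with Fisher's exact
  test and bin-midpoint mapping; Spearman methylation–expression
  correlation; Mann–Whitney group comparisons.
* **Synthetic studies** — a generator that emits every pipeline input with
  planted ground truth (differential probes, enriched feature sets,
  enhancer–promoter pairs, suppressed in-peak methylation), so the whole
  analysis is testable without downloads.

Everything takes data frames and returns tibbles; results have
`tidy()` / `glance()` / `autoplot()` methods.

## Worked example

Generate a synthetic study at the default conditions (19 cases vs 23
controls, 10,000 probes, 500 + 500 planted differential CpGs, 50 planted
enhancer–promoter pairs among 500 decoys) and run the pipeline:

```r
library(inflamethyl)

bundle <- gen_synthetic_study(synth_config(seed = 42))
run <- run_pipeline(bundle, n_perm = 1000, seed = 42)
run
#> <inflamethyl_run>
#> <meth_diff> 10000 probes tested (welch test), 19 case vs 23 control samples
#>   hyper: 500  hypo: 500  unchanged: 9000  (q < 0.05, |delta beta| > 0.15)
#>   enrichment cells: 8 (2 enriched, 1 depleted)
#>   hypermethylated enhancers: 52; links emitted: 50
#>   cross-cohort overlap: min same-direction p = 1.09e-296
#>   RRBS peak-partition KS: D = 0.512, p = 0
#>   truth recovery: sensitivity 1, precision 1, link sensitivity 1
```

All 1,000 planted differential probes are recovered with no false calls.
The enrichment table shows the two planted feature sets detected among the
nulls — hypermethylated probes land in them ~4× more often than the
permutation null expects:

```r
tidy(run$enrichment)
#> # A tibble: 8 x 10
#>   probe_set feature    observed null_mean      z   p_emp direction
#> 1 hyper     enriched_1      258      63.6  20.4   0.004   enriched
#> 3 hyper     enriched_2      255      62.0  25.9   0.002   enriched
#> 5 hyper     null_1           61      51.2   1.45  0.176   none
#> ...
```

The linking stage emits the planted enhancer–promoter pairs (true signal
correlation ≈ 0.9) and the expression join confirms their target genes are
down-regulated:

```r
head(run$links[, c("enh_start", "dhs_start", "r", "r2", "distance", "gene_id")], 3)
#>   enh_start dhs_start     r    r2 distance gene_id
#> 1   2086436   1819272 0.917 0.840   267164 TGT046
#> 2   2336118   2077105 0.906 0.821   259013 TGT028
#> 3   2354138   2684528 0.903 0.815   330390 TGT040

tidy(run$overlap)
#>   a_label b_label n_universe   n_a   n_b     k proportion   p_hyper
#> 1 hyper   hyper        10000   500   500   300        0.6 1.09e-296
#> 2 hyper   hypo         10000   500   500     0        0   1
#> ...
```

The second cohort was generated with 60% directional concordance, and the
overlap table reads it back exactly: 60% same-direction overlap at
astronomical significance, zero cross-direction overlap.

Individual stages are ordinary functions on data frames —
`diff_methylation()`, `enrich_report()`, `call_putative_enhancers()`,
`link_enhancers()`, `directional_overlap()`, `ks_two_sample()`,
`fisher_exact_2x2()`, … — and file readers/writers
(`read_manifest()`, `read_feature_bed()`, `write_synth_bundle()`) handle
the plain TSV/BED formats. See the vignette in `vignettes/` for the
models, conventions and design decisions.

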