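#' False-positive rate of differential calling on null data
#'
#' Generates fully null beta matrices (no planted effects) and reports, per
#' seed, the fraction of probes called hyper or hypo at the default
#' thresholds. With Benjamini-Hochberg FDR control plus the delta-beta
#' filter this fraction should stay well below 1%.
#'
#' @param n_probes,n_case,n_control Study size.
#' @param n_seeds Independent replicates.
#' @param base_seed First seed.
#' @param thresholds A [meth_thresholds()].
#' @return Tibble with one row per seed: `seed`, `n_called`, `frac_called`.
#' @export
assess_null_fdr <- function(n_probes = 10000L, n_case = 20L,
                            n_control = 20L, n_seeds = 10L, base_seed = 1L,
                            thresholds = meth_thresholds()) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg <- synth_config(seed = base_seed + i - 1L, n_probes = n_probes,
                        n_case = n_case, n_control = n_control,
                        frac_hyper = 0, frac_hypo = 0)
    mf <- gen_manifest(cfg)
    truth <- plant_truth(mf$manifest, cfg)
    bm <- gen_beta_matrix(mf$manifest, truth, cfg)
    dm <- diff_methylation(bm$betas, bm$samples, thresholds)
    n_called <- sum(dm$results$label != "unchanged")
    tibble(seed = cfg$seed, n_probes = nrow(dm$results),
           n_called = n_called, frac_called = n_called / nrow(dm$results))
  })
  bind_rows(rows)
}

#' Recovery of planted differential probes
#'
#' Generates a study with planted hyper- and hypomethylated probes and
#' measures direction-aware sensitivity (planted probes recovered with the
#' correct label) and precision (called probes that were planted, in the
#' called direction).
#'
#' @param seed Generator seed.
#' @param n_probes,n_case,n_control,frac_hyper,frac_hypo,effect_delta,beta_concentration
#'   Passed to [synth_config()].
#' @param thresholds A [meth_thresholds()].
#' @return One-row tibble: `n_planted`, `n_called`, `sensitivity`,
#'   `precision`.
#' @export
assess_recovery <- function(seed = 1L, n_probes = 10000L, n_case = 20L,
                            n_control = 20L, frac_hyper = 0.05,
                            frac_hypo = 0.05, effect_delta = 0.25,
                            beta_concentration = 50,
                            thresholds = meth_thresholds()) {
  cfg <- synth_config(seed = seed, n_probes = n_probes, n_case = n_case,
                      n_control = n_control, frac_hyper = frac_hyper,
                      frac_hypo = frac_hypo, effect_delta = effect_delta,
                      beta_concentration = beta_concentration)
  mf <- gen_manifest(cfg)
  truth <- plant_truth(mf$manifest, cfg)
  bm <- gen_beta_matrix(mf$manifest, truth, cfg)
  dm <- diff_methylation(bm$betas, bm$samples, thresholds)
  called_hyper <- called_probes(dm, "hyper")
  called_hypo <- called_probes(dm, "hypo")
  tp <- length(intersect(called_hyper, truth$hyper_probes)) +
    length(intersect(called_hypo, truth$hypo_probes))
  n_planted <- length(truth$hyper_probes) + length(truth$hypo_probes)
  n_called <- length(called_hyper) + length(called_hypo)
  tibble(seed = seed, n_planted = n_planted, n_called = n_called,
         sensitivity = tp / n_planted,
         precision = if (n_called > 0) tp / n_called else NA_real_)
}

#' Calibration of the permutation enrichment Z-score under the null
#'
#' Repeatedly draws a probe set uniformly from the manifest (so it is
#' itself a null draw), runs the permutation enrichment against a fixed
#' feature set covering roughly `coverage` of the background, and records
#' the Z-score and one-sided (enrichment) empirical p per run. Under the
#' null, |Z| should rarely exceed 3 and the empirical p should be
#' approximately uniform.
#'
#' @param n_runs Independent null runs.
#' @param k Probe-set size per run.
#' @param n_probes Manifest size.
#' @param coverage Base coverage rate of the feature set.
#' @param n_perm Permutations per run.
#' @param seed Master seed.
#' @return Tibble with one row per run: `run`, `observed`, `z`, `p_emp`.
#' @export
assess_enrichment_null <- function(n_runs = 200L, k = 500L,
                                   n_probes = 10000L, coverage = 0.1,
                                   n_perm = 1000L, seed = 1L) {
  cfg <- synth_config(seed = seed, n_probes = n_probes,
                      frac_hyper = 0, frac_hypo = 0,
                      feature_base_rate = coverage, enrichment_fold = 1,
                      n_enriched_features = 1L, n_null_features = 1L)
  mf <- gen_manifest(cfg)
  truth <- plant_truth(mf$manifest, cfg)
  fs <- gen_feature_sets(mf$manifest, truth, cfg)[["null_1"]]
  hit <- position_overlaps(mf$manifest[, c("chrom", "pos")], fs)
  n <- length(hit)
  rows <- withr::with_seed(seed + 1000L, {
    lapply(seq_len(n_runs), function(run) {
      probe_idx <- sample.int(n, k)
      obs <- sum(hit[probe_idx])
      null <- vapply(seq_len(n_perm),
                     function(i) sum(hit[sample.int(n, k)]), integer(1))
      r <- enrichment_z(obs, null, alternative = "enrichment")
      tibble(run = run, observed = obs, z = r$z, p_emp = r$p_emp)
    })
  })
  bind_rows(rows)
}

#' Detection of planted feature-set enrichment
#'
#' For each seed, generates a manifest with planted hyper probes and a
#' feature set over-representing them `enrichment_fold`-fold, then runs the
#' permutation enrichment of the planted set against the array background.
#'
#' @param n_seeds Independent generations.
#' @param base_seed First seed.
#' @param n_probes Manifest size.
#' @param frac_hyper Planted fraction.
#' @param coverage Base coverage rate.
#' @param enrichment_fold Planted over-representation.
#' @param n_perm Permutations per run.
#' @return Tibble per seed: `seed`, `observed`, `z`, `p_emp`.
#' @export
assess_enrichment_planted <- function(n_seeds = 20L, base_seed = 1L,
                                      n_probes = 10000L, frac_hyper = 0.05,
                                      coverage = 0.1, enrichment_fold = 5,
                                      n_perm = 1000L) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg <- synth_config(seed = base_seed + i - 1L, n_probes = n_probes,
                        frac_hyper = frac_hyper, frac_hypo = 0,
                        feature_base_rate = coverage,
                        enrichment_fold = enrichment_fold,
                        n_enriched_features = 1L, n_null_features = 0L)
    mf <- gen_manifest(cfg)
    truth <- plant_truth(mf$manifest, cfg)
    fs <- gen_feature_sets(mf$manifest, truth, cfg)[["enriched_1"]]
    obs <- observed_overlap(truth$hyper_probes, mf$manifest, fs)
    null <- permutation_null(length(truth$hyper_probes), mf$manifest, fs,
                             n_perm = n_perm, seed = cfg$seed + 500L)
    r <- enrichment_z(obs, null, alternative = "enrichment")
    tibble(seed = cfg$seed, observed = obs, z = r$z, p_emp = r$p_emp)
  })
  bind_rows(rows)
}

#' Recovery of planted enhancer-promoter links
#'
#' Generates the DHS signal matrix with planted pairs and decoys, links
#' every planted enhancer, and reports sensitivity (planted pairs emitted
#' at the r-squared threshold, with the planted gene assigned) and the
#' fraction of emitted links that are decoys (any emitted link whose target
#' site is not the planted promoter of its anchor).
#'
#' @param seed Generator seed.
#' @param config A [synth_config()]; its link fields set the problem size.
#' @param link_cfg A [link_config()].
#' @return One-row tibble: `n_planted`, `n_emitted`, `sensitivity`,
#'   `decoy_fraction`.
#' @export
assess_link_recovery <- function(seed = 1L, config = NULL,
                                 link_cfg = link_config()) {
  if (is.null(config)) config <- synth_config(seed = seed)
  mf <- gen_manifest(config)
  truth <- plant_truth(mf$manifest, config)
  dhs <- gen_dhs_signal(mf$manifest, truth, config)
  links <- link_enhancers(dhs$anchors, dhs$signal, dhs$target_genes,
                          link_cfg)
  planted <- dhs$links
  key <- function(chrom, a, b, g) paste(chrom, a, b, g, sep = ":")
  planted_keys <- key(planted$enh_chrom, planted$enh_start, planted$enh_end,
                      planted$gene_id)
  emitted_keys <- key(links$enh_chrom, links$enh_start, links$enh_end,
                      links$gene_id)
  recovered <- planted_keys %in% emitted_keys
  # a "true" emitted link targets its anchor's planted promoter site
  true_target <- paste(links$enh_start, links$dhs_start) %in%
    paste(planted$enh_start, planted$prom_start)
  tibble(seed = seed, n_planted = nrow(planted), n_emitted = nrow(links),
         sensitivity = mean(recovered),
         decoy_fraction = if (nrow(links) > 0) mean(!true_target)
                          else NA_real_)
}

#' RRBS peak/methylation exclusivity across effect levels
#'
#' For each exclusivity level, generates RRBS records over a fixed peak
#' set, applies the coverage filter, partitions by peak overlap and runs
#' the two-sample Kolmogorov-Smirnov test. The KS statistic should grow
#' monotonically with the planted exclusivity.
#'
#' @param levels Exclusivity levels in `[0, 1]`.
#' @param n_rrbs Records per level (sized so both arms are comfortably
#'   populated after filtering).
#' @param seed Generator seed.
#' @param min_cov Coverage filter.
#' @return Tibble per level: `exclusivity`, `n_in`, `n_out`, `D`, `p`.
#' @export
assess_rrbs_exclusivity <- function(levels = c(0, 0.25, 0.5, 0.75, 1),
                                    n_rrbs = 40000L, seed = 1L,
                                    min_cov = 5L) {
  rows <- lapply(seq_along(levels), function(i) {
    cfg <- synth_config(seed = seed, n_rrbs = n_rrbs,
                        exclusivity_strength = levels[i])
    peaks <- gen_peak_set(cfg, coverage_fraction = 0.2)
    rec <- gen_rrbs(peaks, cfg, seed = cfg$seed + 6L + i)
    rec <- filter_coverage(rec, min_cov = min_cov)
    rec <- partition_by_peaks(rec, peaks)
    ks <- ks_two_sample(rec$beta[rec$in_peak], rec$beta[!rec$in_peak])
    tibble(exclusivity = levels[i], n_in = sum(rec$in_peak),
           n_out = sum(!rec$in_peak), D = ks$D, p = ks$p)
  })
  bind_rows(rows)
}
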