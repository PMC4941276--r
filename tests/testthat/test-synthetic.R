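small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_probes = 2000L, n_cgi = 60L, n_genes = 30L,
         n_planted_links = 10L, n_decoy_dhs = 80L, n_cell_lines = 40L,
         n_rrbs = 4000L),
    list(...))
  do.call(synth_config, args)
}

test_that("manifest generation is deterministic and annotation is complete", {
  cfg <- small_cfg(seed = 5)
  m1 <- gen_manifest(cfg)
  m2 <- gen_manifest(cfg)
  expect_identical(m1$manifest, m2$manifest)
  expect_identical(as.data.frame(m1$cgi), as.data.frame(m2$cgi))
  expect_false(anyNA(m1$manifest$cgi_context))
  expect_false(anyNA(m1$manifest$gene_context))
  expect_equal(anyDuplicated(m1$manifest$pos), 0)
  # annotation agrees with a fresh re-annotation of the emitted positions
  expect_equal(m1$manifest$cgi_context,
               annotate_cgi_context(m1$manifest, m1$cgi))
  expect_equal(m1$manifest$gene_context,
               annotate_gene_context(m1$manifest, m1$genes))
})

test_that("all four CGI and gene context classes occur at default scale", {
  mf <- gen_manifest(synth_config(seed = 2))
  expect_true(all(table(mf$manifest$cgi_context) > 0))
  expect_true(all(table(mf$manifest$gene_context) > 0))
})

test_that("beta matrix respects range, planted effect size and determinism", {
  cfg <- small_cfg(seed = 7, n_case = 20L, n_control = 20L)
  mf <- gen_manifest(cfg)
  truth <- plant_truth(mf$manifest, cfg)
  b1 <- gen_beta_matrix(mf$manifest, truth, cfg)
  b2 <- gen_beta_matrix(mf$manifest, truth, cfg)
  expect_identical(b1$betas, b2$betas)
  vals <- as.matrix(b1$betas[, b1$samples$sample_id])
  expect_true(all(vals >= 0 & vals <= 1))
  # generator calibration: empirical mean delta over planted hyper probes
  case_ids <- b1$samples$sample_id[b1$samples$group == "case"]
  ctrl_ids <- b1$samples$sample_id[b1$samples$group == "control"]
  idx <- match(truth$hyper_probes, b1$betas$probe_id)
  d <- rowMeans(as.matrix(b1$betas[idx, case_ids])) -
    rowMeans(as.matrix(b1$betas[idx, ctrl_ids]))
  expect_lt(abs(mean(d) - cfg$effect_delta), 0.03)
})

test_that("a zero-effect generator yields an indistinguishable cohort", {
  cfg <- small_cfg(seed = 19, effect_delta = 0, n_case = 20L,
                   n_control = 20L)
  mf <- gen_manifest(cfg)
  truth <- plant_truth(mf$manifest, cfg)
  bm <- gen_beta_matrix(mf$manifest, truth, cfg)
  dm <- diff_methylation(bm$betas, bm$samples)
  expect_lt(mean(dm$results$label != "unchanged"), 0.01)
})

test_that("feature sets hit their planted coverage rates", {
  cfg <- small_cfg(seed = 23, frac_hyper = 0.1)
  mf <- gen_manifest(cfg)
  truth <- plant_truth(mf$manifest, cfg)
  fs <- gen_feature_sets(mf$manifest, truth, cfg)
  expect_named(fs, c("enriched_1", "enriched_2", "null_1", "null_2"))
  is_hyper <- mf$manifest$probe_id %in% truth$hyper_probes
  cov_hyper <- mean(position_overlaps(mf$manifest[is_hyper, ],
                                      fs$enriched_1))
  cov_bg <- mean(position_overlaps(mf$manifest[!is_hyper, ],
                                   fs$enriched_1))
  rate <- cfg$feature_base_rate
  n_h <- sum(is_hyper); n_b <- sum(!is_hyper)
  expect_lt(abs(cov_hyper - rate * 5), 4 * sqrt(rate * 5 * (1 - rate * 5) / n_h))
  expect_lt(abs(cov_bg - rate), 4 * sqrt(rate * (1 - rate) / n_b))
  expect_error(synth_config(feature_base_rate = 0.3, enrichment_fold = 5),
               "infeasible")
})

test_that("DHS signal matrix encodes planted correlations and clean decoys", {
  cfg <- small_cfg(seed = 29, n_cell_lines = 100L)
  mf <- gen_manifest(cfg)
  truth <- plant_truth(mf$manifest, cfg)
  dhs <- gen_dhs_signal(mf$manifest, truth, cfg)
  cells <- grep("^cell_", names(dhs$signal), value = TRUE)
  sig <- as.matrix(dhs$signal[, cells])
  key <- paste(dhs$signal$start, dhs$signal$end)
  kind <- dhs$site_kinds$site_kind[match(key, paste(dhs$site_kinds$start,
                                                    dhs$site_kinds$end))]
  anchors <- which(kind == "anchor"); proms <- which(kind == "promoter")
  # match anchor i to its planted promoter via the truth table
  r_planted <- vapply(seq_len(nrow(dhs$links)), function(i) {
    ai <- which(dhs$signal$start == dhs$links$enh_start[i])[1]
    pi <- which(dhs$signal$start == dhs$links$prom_start[i])[1]
    cor(sig[ai, ], sig[pi, ])
  }, numeric(1))
  expect_gt(mean(r_planted), 0.85)
  expect_lt(mean(r_planted), 0.95)
  # decoy-anchor correlations rarely cross the linking threshold
  decoys <- which(kind == "decoy")
  r_decoy <- as.vector(cor(t(sig[anchors, ]), t(sig[decoys, ])))
  expect_lt(mean(r_decoy^2 >= 0.7), 0.01)
  expect_true(all(sig >= 0))
})

test_that("RRBS generator spans the exclusivity dial", {
  cfg0 <- small_cfg(seed = 31, exclusivity_strength = 0, n_rrbs = 10000L)
  peaks <- gen_peak_set(cfg0, coverage_fraction = 0.2)
  r0 <- partition_by_peaks(gen_rrbs(peaks, cfg0), peaks)
  ks0 <- ks_two_sample(r0$beta[r0$in_peak], r0$beta[!r0$in_peak])
  expect_lt(ks0$D, 0.05)

  cfg1 <- small_cfg(seed = 31, exclusivity_strength = 1, n_rrbs = 10000L)
  r1 <- partition_by_peaks(gen_rrbs(peaks, cfg1), peaks)
  expect_lt(mean(r1$beta[r1$in_peak]), 0.2)
  ks1 <- ks_two_sample(r1$beta[r1$in_peak], r1$beta[!r1$in_peak])
  expect_lt(ks1$p, 1e-6)
  # the sub-5X fraction matches its configured rate within binomial error
  lowfrac <- mean(r1$coverage < 5)
  expect_lt(abs(lowfrac - cfg1$low_coverage_frac),
            4 * sqrt(0.2 * 0.8 / nrow(r1)))
})

test_that("expression table covers all genes with planted down-regulation", {
  cfg <- small_cfg(seed = 37)
  genes <- gene_models(sprintf("G%03d", 1:200), rep("chr1", 200),
                       rep("+", 200), seq(1000L, by = 10000L, length = 200),
                       as.list(seq(1000L, by = 10000L, length = 200)),
                       as.list(seq(1500L, by = 10000L, length = 200)))
  down <- genes$gene_id[1:40]
  expr <- gen_expression(genes, down, cfg)
  expect_equal(sort(expr$gene_id), sort(genes$gene_id))
  planted <- expr[expr$gene_id %in% down, ]
  others <- expr[!expr$gene_id %in% down, ]
  expect_gte(mean(planted$p_adj < 0.05 & planted$fold_change < 1), 0.9)
  expect_lt(mean(others$p_adj < 0.05), 0.15)
})

test_that("bundle writing is byte-identical across repeated generation", {
  cfg <- small_cfg(seed = 41, n_rrbs = 1000L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synth_bundle(gen_synthetic_study(cfg), d1)
  write_synth_bundle(gen_synthetic_study(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) >= 12)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and the written manifest reads back to the in-memory one
  m <- read_manifest(file.path(d1, "manifest.tsv"))
  b <- gen_synthetic_study(cfg)
  expect_equal(m$pos, b$manifest$pos)
})
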