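test_that("putative enhancers are DHS with zero H3K4me3 overlap", {
  dhs <- feature_set(tibble::tibble(chrom = "chr1",
                                    start = c(100L, 500L, 900L),
                                    end = c(200L, 600L, 1000L)), name = "dhs")
  k4 <- feature_set(tibble::tibble(chrom = "chr1", start = 150L, end = 250L))
  out <- call_putative_enhancers(dhs, k4)
  expect_equal(out$start, c(500L, 900L))
  # empty promoter mark keeps everything; output is a subset; idempotent
  expect_equal(nrow(call_putative_enhancers(dhs, k4[0, ])), 3)
  again <- call_putative_enhancers(out, k4)
  expect_equal(as.data.frame(again[, 1:3]), as.data.frame(out[, 1:3]),
               ignore_attr = TRUE)
})

test_that("putative-enhancer calling matches a brute-force overlap filter", {
  fx1 <- random_interval_fixture(200, 200, seed = 31)
  dhs <- fx1$features
  k4 <- random_interval_fixture(1, 50, seed = 32)$features
  got <- call_putative_enhancers(dhs, k4)
  keep <- vapply(seq_len(nrow(dhs)), function(i) {
    !any(k4$chrom == dhs$chrom[i] & k4$start < dhs$end[i] &
           dhs$start[i] < k4$end)
  }, logical(1))
  expect_equal(as.data.frame(got[, 1:3]),
               as.data.frame(dhs[keep, 1:3]), ignore_attr = TRUE)
})

test_that("hypermethylated enhancers are kept once however many probes inside", {
  enh <- feature_set(tibble::tibble(chrom = "chr1",
                                    start = c(100L, 1000L),
                                    end = c(400L, 1100L)))
  manifest <- tibble::tibble(probe_id = c("a", "b", "c", "d"),
                             chrom = "chr1",
                             pos = c(150L, 200L, 300L, 5000L))
  out <- hypermethylated_enhancers(enh, c("a", "b", "c"), manifest)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 100L)
  none <- hypermethylated_enhancers(enh, "d", manifest)
  expect_equal(nrow(none), 0)
  expect_error(hypermethylated_enhancers(enh, "zz", manifest),
               "not in manifest")
})

test_that("pearson_r reproduces hand-computed and degenerate cases", {
  expect_equal(pearson_r(1:5, 2 * (1:5)), 1)
  expect_equal(pearson_r(1:4, c(4, 3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1:2, 1:2), ">= 3")
})

make_signal <- function(n_extra_cells = 0) {
  # anchor at site 1; site 2 perfectly correlated, near a TSS; site 3
  # anti-correlated but beyond the window; site 4 uncorrelated decoy
  withr::with_seed(8, {
    a <- runif(10, 1, 5)
    tibble::tibble(
      chrom = "chr1",
      start = c(100000L, 300000L, 700000L, 250000L),
      end = c(100150L, 300150L, 700150L, 250150L)) |>
      dplyr::bind_cols(tibble::as_tibble(as.data.frame(rbind(
        a, a * 2 + 1, rev(a), runif(10, 1, 5)))) |>
          stats::setNames(sprintf("cell_%02d", 1:10)))
  })
}

test_that("linking honours the window, threshold and gene assignment", {
  sig <- make_signal()
  genes <- gene_models(c("G1", "G2"), c("chr1", "chr1"), c("+", "+"),
                       tss = c(301000L, 699000L),
                       exon_starts = list(301000L, 699000L),
                       exon_ends = list(301500L, 699500L))
  anchor <- tibble::tibble(chrom = "chr1", start = 100000L, end = 100150L)
  links <- link_enhancer_targets(anchor, sig, genes)
  # only the in-window correlated site is emitted; the anti-correlated site
  # sits 600 kb away and must be excluded despite r^2 = 1
  expect_equal(nrow(links), 1)
  expect_equal(links$dhs_start, 300000L)
  expect_equal(links$r, 1)
  expect_equal(links$gene_id, "G1")  # TSS 925 bp from the site midpoint
  expect_true(all(links$distance <= 500000))
  expect_true(all(links$r2 >= 0.7))
  expect_error(
    link_enhancer_targets(tibble::tibble(chrom = "chr5", start = 1L,
                                         end = 10L), sig, genes),
    "does not overlap")
})

test_that("the r-squared boundary includes 0.7056 and excludes 0.6889", {
  withr::with_seed(13, {
    n <- 40
    x <- rnorm(n)
    make_y <- function(target_r) {
      # construct y with exact sample correlation target_r
      e <- rnorm(n)
      e <- residuals(lm(e ~ x))
      x0 <- scale(x)[, 1]; e0 <- scale(e)[, 1]
      target_r * x0 + sqrt(1 - target_r^2) * e0
    }
    base <- abs(min(c(x, make_y(0.84), make_y(0.83)))) + 1
    sig <- tibble::tibble(chrom = "chr1",
                          start = c(1000L, 5000L, 9000L),
                          end = c(1100L, 5100L, 9100L))
    vals <- rbind(x, make_y(0.84), make_y(0.83)) + base
    sig <- dplyr::bind_cols(sig, tibble::as_tibble(as.data.frame(vals)) |>
                              stats::setNames(sprintf("c%02d", 1:n)))
    anchor <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1100L)
    links <- link_enhancer_targets(anchor, sig,
                                   gene_models("g", "chr1", "+", 1L,
                                               list(1L), list(10L)))
    expect_equal(nrow(links), 1)
    expect_equal(links$dhs_start, 5000L)
    expect_equal(links$r2, 0.84^2, tolerance = 1e-10)
  })
})

test_that("planted pairs are recovered from decoys at small scale", {
  cfg <- synth_config(seed = 17, n_probes = 3000, n_planted_links = 10,
                      n_decoy_dhs = 100, n_cell_lines = 60,
                      n_cgi = 50L, n_genes = 20L)
  out <- assess_link_recovery(seed = 17, config = cfg)
  expect_gte(out$sensitivity, 0.9)
  expect_lte(out$decoy_fraction, 0.1)
  # every emitted link satisfies the window and threshold invariants
  mf <- gen_manifest(cfg)
  truth <- plant_truth(mf$manifest, cfg)
  dhs <- gen_dhs_signal(mf$manifest, truth, cfg)
  links <- link_enhancers(dhs$anchors, dhs$signal, dhs$target_genes)
  expect_true(all(links$r2 >= 0.7))
  expect_true(all(links$distance <= 500000))
  expect_equal(links$r2, links$r^2)
})
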