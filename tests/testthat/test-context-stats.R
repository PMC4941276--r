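test_that("coverage filter is inclusive at the 5X boundary", {
  rec <- tibble::tibble(chrom = "chr1", pos = 1:3 * 10L,
                        coverage = c(3L, 5L, 10L), beta = c(0.1, 0.5, 0.9))
  out <- filter_coverage(rec)
  expect_equal(out$coverage, c(5L, 10L))
  expect_equal(nrow(filter_coverage(rec, min_cov = 4)), 2)
  expect_equal(nrow(filter_coverage(rec, min_cov = 3)), 3)
})

test_that("peak partition is disjoint and exhaustive and matches brute force", {
  fx <- random_interval_fixture(400, 50, seed = 41)
  rec <- dplyr::mutate(fx$positions, coverage = 10L,
                       beta = runif(dplyr::n()))
  part <- partition_by_peaks(rec, fx$features)
  expect_equal(sum(part$in_peak) + sum(!part$in_peak), nrow(rec))
  expect_equal(part$in_peak, oracle_overlap(rec, fx$features))
  # degenerate peak sets
  none <- partition_by_peaks(rec, fx$features[0, ])
  expect_false(any(none$in_peak))
  all_p <- partition_by_peaks(
    rec, feature_set(tibble::tibble(chrom = c("chr1", "chr2"), start = 0,
                                    end = 200000L)))
  expect_true(all(all_p$in_peak))
})

test_that("KS statistic equals the hand-enumerated ECDF supremum", {
  a <- c(0.1, 0.4, 0.7); b <- c(0.2, 0.5)
  got <- ks_two_sample(a, b)
  grid <- sort(unique(c(a, b)))
  d_hand <- max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x),
                           numeric(1))))
  expect_equal(got$D, d_hand)
  expect_equal(ks_two_sample(a, a)$D, 0)
  expect_equal(ks_two_sample(a, a)$p, 1)
  expect_equal(ks_two_sample(c(0.1, 0.2), c(0.5, 0.9))$D, 1)
  expect_error(ks_two_sample(numeric(), a), "non-empty")
})

test_that("Fisher 2x2 matches exhaustive enumeration for small totals", {
  withr::with_seed(43, {
    for (i in 1:200) {
      tab <- as.vector(stats::rmultinom(1, sample(4:20, 1), rep(0.25, 4)))
      got <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
      expect_equal(got, oracle_fisher_2x2(tab[1], tab[2], tab[3], tab[4]),
                   tolerance = 1e-9,
                   label = paste(tab, collapse = ","))
    }
  })
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "positive")
})

test_that("Fisher and hypergeometric share the same point mass", {
  # P(X = k) via the Fisher enumeration kernel equals dhyper on a grid
  for (N in c(10, 15, 20)) {
    for (K in c(3, 7)) {
      for (n in c(4, 8)) {
        for (k in 0:min(K, n)) {
          expect_equal(oracle_dhyper(k, K, n, N),
                       stats::dhyper(k, K, N - K, n), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the published MS-HRM table is strongly significant", {
  # 41/44 healthy completely unmethylated vs 23/46 inflamed
  expect_lt(fisher_exact_2x2(41, 3, 23, 23), 0.001)
})

test_that("MS-HRM midpoints are the bin-edge means", {
  expect_equal(hrm_midpoint("0-5"), 2.5)
  expect_equal(hrm_midpoint("6-10"), 8)
  expect_equal(hrm_midpoint("11-25"), 18)
  expect_equal(hrm_midpoint("26-50"), 38)
  cats <- hrm_categories()
  expect_equal(cats$midpoint, (cats$lower + cats$upper) / 2)
  expect_error(hrm_midpoint("51-100"), "unknown")
})

test_that("Spearman uses mid-ranks and handles monotone/constant inputs", {
  expect_equal(spearman_corr(1:5, c(2, 4, 9, 16, 30)), 1)
  expect_equal(spearman_corr(1:5, 5:1), -1)
  x <- c(1, 2, 2, 4); y <- c(10, 9, 7, 5)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(4, 3, 2, 1)  # hand mid-ranks
  expect_equal(spearman_corr(x, y), cor(rx, ry))
  expect_true(is.na(spearman_corr(c(1, 1, 1), 1:3)))
})

test_that("Mann-Whitney U matches brute-force pair counting", {
  a <- c(1, 3, 5); b <- c(2, 4)
  got <- mann_whitney(a, b)
  u_hand <- sum(outer(a, b, ">"))  # pairs where a beats b
  expect_equal(got$U, u_hand)
  expect_equal(mann_whitney(c(1, 2, 3), c(10, 20))$U, 0)
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.9)
  expect_error(mann_whitney(numeric(), a), "non-empty")
})

test_that("target-expression joins label direction and flag missing genes", {
  links <- tibble::tibble(gene_id = c("G1", "G2", "G3", NA, "G1"))
  expr <- tibble::tibble(gene_id = c("G1", "G2"),
                         fold_change = c(0.5, 1.4), p_adj = c(0.01, 0.02))
  out <- target_expression_summary(links, expr)
  expect_equal(nrow(out), 3)  # unique non-NA genes
  expect_equal(out$direction[out$gene_id == "G1"], "down")
  expect_equal(out$direction[out$gene_id == "G2"], "up")
  expect_false(out$in_expr[out$gene_id == "G3"])
  expect_true(is.na(out$direction[out$gene_id == "G3"]))
})

test_that("RRBS reader validates beta range", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = 1:2,
                                  coverage = c(5L, 9L),
                                  beta = c(0.2, 0.9)), path)
  r <- read_rrbs(path)
  expect_equal(nrow(r), 2)
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = 1L,
                                  coverage = 5L, beta = 1.5), path)
  expect_error(read_rrbs(path), "\\[0, 1\\]")
})
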