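test_that("BED reading sorts intervals, skips headers and round-trips", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=test", "chr1\t100\t200", "chr1\t50\t80",
               "# comment", "chr2\t10\t20"), path)
  fs <- read_feature_bed(path, name = "toy")
  expect_s3_class(fs, "feature_set")
  expect_equal(set_name(fs), "toy")
  expect_equal(fs$start, c(50L, 100L, 10L))
  expect_equal(fs$chrom, c("chr1", "chr1", "chr2"))

  out <- withr::local_tempfile(fileext = ".bed")
  write_feature_bed(fs, out)
  expect_equal(as.data.frame(read_feature_bed(out)[, 1:3]),
               as.data.frame(fs[, 1:3]), ignore_attr = TRUE)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_equal(nrow(read_feature_bed(empty)), 0)
})

test_that("malformed BED lines raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), path)
  expect_error(read_feature_bed(path), "line 2")
  writeLines(c("chr1\tfoo\t200"), path)
  expect_error(read_feature_bed(path), "non-integer")
  writeLines(c("chr1\t100"), path)
  expect_error(read_feature_bed(path), ">= 3 fields")
})

test_that("position overlap is half-open at single-base resolution", {
  fs <- feature_set(tibble::tibble(chrom = "chr1", start = 100, end = 200))
  pos <- tibble::tibble(chrom = "chr1", pos = c(99L, 100L, 150L, 199L, 200L))
  expect_equal(position_overlaps(pos, fs), c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("overlap and nearest-distance match brute-force scans on random fixtures", {
  for (seed in 1:4) {
    fx <- random_interval_fixture(n_pos = 250, n_feat = 60, seed = seed)
    expect_equal(position_overlaps(fx$positions, fx$features),
                 oracle_overlap(fx$positions, fx$features))
    expect_equal(distance_to_nearest(fx$positions, fx$features),
                 oracle_distance(fx$positions, fx$features))
  }
})

test_that("distance handles inside, right-gap and empty-chromosome cases", {
  fs <- feature_set(tibble::tibble(chrom = "chr1", start = 100, end = 200))
  pos <- tibble::tibble(chrom = c("chr1", "chr1", "chr9"),
                        pos = c(150L, 300L, 5L))
  expect_equal(distance_to_nearest(pos, fs), c(0L, 100L, NA_integer_))
})

test_that("CGI context boundaries follow the shore/shelf/open-sea bands", {
  cgi <- feature_set(tibble::tibble(chrom = "chr1", start = 1000, end = 2000))
  # right-side gap for position p is p - end
  d_to_pos <- function(d) 2000L + d
  pos <- tibble::tibble(chrom = "chr1",
                        pos = c(1500L, d_to_pos(c(1L, 2000L, 2001L, 4000L,
                                                  4001L))))
  ctx <- annotate_cgi_context(pos, cgi)
  expect_equal(as.character(ctx),
               c("island", "shore", "shore", "shelf", "shelf", "open_sea"))
  # a probe on a CGI-free chromosome is open sea
  off <- tibble::tibble(chrom = "chrX", pos = 1L)
  expect_equal(as.character(annotate_cgi_context(off, cgi)), "open_sea")
})

test_that("CGI context is a partition over any probe set", {
  fx <- random_interval_fixture(n_pos = 500, n_feat = 30, seed = 9)
  ctx <- annotate_cgi_context(fx$positions, fx$features)
  expect_false(anyNA(ctx))
  expect_equal(sum(table(ctx)), nrow(fx$positions))
})

test_that("gene context applies promoter > exon > intron precedence", {
  genes <- gene_models(
    gene_id = c("A", "B"), chrom = c("chr1", "chr1"),
    strand = c("+", "+"), tss = c(10000L, 50000L),
    exon_starts = list(c(10000L, 13000L), c(50000L, 60000L)),
    exon_ends = list(c(10500L, 13400L), c(50200L, 60400L)))
  pos <- tibble::tibble(chrom = "chr1",
                        pos = c(9000L,   # 1 kb upstream of A's TSS
                                13100L,  # inside A's 2nd exon, 3.1 kb from TSS
                                12600L,  # in A's span, no exon, > 2.5 kb
                                         # from the TSS -> intron
                                60100L,  # exon of B, 10 kb from B's TSS
                                300000L  # nowhere
                        ))
  expect_equal(as.character(annotate_gene_context(pos, genes)),
               c("promoter", "exon", "intron", "exon", "intergenic"))
  # promoter wins over intron of another gene: place a probe in B's intron
  # but within 2.5 kb of A's TSS
  genes2 <- gene_models(
    gene_id = c("A", "B"), chrom = c("chr1", "chr1"),
    strand = c("+", "+"), tss = c(10000L, 5000L),
    exon_starts = list(10000L, c(5000L, 15000L)),
    exon_ends = list(10500L, c(5200L, 15400L)))
  probe <- tibble::tibble(chrom = "chr1", pos = 9000L) # B-intron, A-promoter
  expect_equal(as.character(annotate_gene_context(probe, genes2)),
               "promoter")
})

test_that("manifest positions are converted from 1-based on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(probe_id = c("cg1", "cg2"),
                                  chrom = "chr1", pos = c(101L, 201L)), path)
  expect_equal(read_manifest(path, base = 1)$pos, c(100L, 200L))
  expect_equal(read_manifest(path, base = 0)$pos, c(101L, 201L))
})

test_that("gene models validate exon structure and round-trip via TSV", {
  expect_error(gene_models("g", "chr1", "+", 10L, list(c(100L, 50L)),
                           list(c(200L, 150L))), "sorted")
  g <- gene_models(c("g2", "g1"), c("chr1", "chr1"), c("+", "-"),
                   c(100L, 900L), list(100L, c(300L, 600L)),
                   list(200L, c(400L, 900L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(g, path)
  g2 <- read_gene_models(path)
  expect_equal(g2$gene_id, g$gene_id)
  expect_equal(g2$exon_starts, g$exon_starts)
})
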