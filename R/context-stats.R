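#' Filter per-CpG bisulfite records by read coverage
#'
#' Keeps records with `coverage >= min_cov` (default 5, i.e. "at least 5X"),
#' preserving order.
#'
#' @param records Tibble of per-CpG records with a `coverage` column
#'   (typically `chrom`, `pos`, `coverage`, `beta`).
#' @param min_cov Minimum coverage, inclusive.
#' @return The filtered tibble.
#' @export
filter_coverage <- function(records, min_cov = 5L) {
  stopifnot("coverage" %in% names(records))
  as_tibble(records)[records$coverage >= min_cov, , drop = FALSE]
}

#' Partition CpG records by binding-peak overlap
#'
#' Splits per-CpG methylation records into those falling inside a peak set
#' (e.g. CTCF / RAD21 / SMC3 binding sites) and those outside; the partition
#' is disjoint and exhaustive.
#'
#' @param records Tibble with `chrom`, `pos` and `beta` columns.
#' @param peaks A `feature_set` of binding peaks.
#' @return `records` with a logical `in_peak` column added.
#' @export
partition_by_peaks <- function(records, peaks) {
  records <- as_tibble(records)
  stopifnot(all(c("chrom", "pos", "beta") %in% names(records)))
  records$in_peak <- position_overlaps(records[, c("chrom", "pos")], peaks)
  records
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sided p-value (the
#' intended sample sizes are 1e5-1e6 CpGs per arm, where the asymptotic
#' distribution is exact for practical purposes).
#'
#' @param a,b Non-empty numeric vectors.
#' @return One-row tibble with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  k <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble(D = unname(k$statistic), p = k$p.value)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' @param tab A 2x2 matrix of non-negative counts, or the four counts
#'   `a, b, c, d` given row-wise.
#' @param b,c,d Optional remaining cells when `tab` is given as the scalar
#'   `a`.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(41, 3, 23, 23), nrow = 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.matrix(tab)) {
    tab <- matrix(c(tab, b, c, d), nrow = 2, byrow = TRUE)
  }
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("need a 2x2 table of non-negative integer counts")
  }
  if (sum(tab) == 0) abort("table total must be positive")
  fisher.test(tab)$p.value
}

#' MS-HRM methylation categories and their midpoints
#'
#' The methylation-sensitive high-resolution melting assay reports each
#' sample in one of four percent-methylation bins; the numeric value used
#' downstream is the arithmetic mean of the bin edges (so the 0-5% bin maps
#' to 2.5%).
#'
#' @return A tibble with `category`, `lower`, `upper`, `midpoint` (percent).
#' @export
hrm_categories <- function() {
  tibble(category = c("0-5", "6-10", "11-25", "26-50"),
         lower = c(0, 6, 11, 26),
         upper = c(5, 10, 25, 50),
         midpoint = c(2.5, 8, 18, 38))
}

#' Midpoint of an MS-HRM category
#'
#' @param category One of `"0-5"`, `"6-10"`, `"11-25"`, `"26-50"`.
#' @return Midpoint percent value.
#' @examples
#' hrm_midpoint("0-5") # 2.5
#' @export
hrm_midpoint <- function(category) {
  cats <- hrm_categories()
  idx <- match(category, cats$category)
  if (anyNA(idx)) {
    abort(paste0("unknown MS-HRM category; expected one of ",
                 paste(cats$category, collapse = ", ")))
  }
  cats$midpoint[idx]
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); `NA` when
#' either vector is constant.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return rho in `[-1, 1]`, or `NA`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length vectors of length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups; exact enumeration when
#' `length(a) * length(b) <= 400` and there are no ties, otherwise the
#' tie-corrected normal approximation. The reported `U` counts pairs where
#' an `a` observation exceeds a `b` observation.
#'
#' @param a,b Non-empty numeric vectors.
#' @return One-row tibble with `U` and two-sided `p`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  use_exact <- length(a) * length(b) <= 400 &&
    !any(duplicated(c(a, b)))
  w <- suppressWarnings(wilcox.test(a, b, exact = use_exact, correct = TRUE))
  tibble(U = unname(w$statistic), p = w$p.value)
}

#' Join enhancer-linked genes onto expression statistics
#'
#' Takes the genes assigned by the enhancer-linking stage and annotates them
#' with expression fold change and adjusted p (e.g. a disease-vs-healthy
#' expression meta-analysis). Genes absent from the expression table are
#' kept and flagged rather than silently dropped.
#'
#' @param links Link tibble from [link_enhancers()] (uses its `gene_id`
#'   column).
#' @param expr Expression table: `gene_id`, `fold_change`, `p_adj`.
#' @param p_max Adjusted-p threshold for calling a direction.
#' @return Tibble `gene_id`, `fold_change`, `p_adj`, `in_expr`, `direction`
#'   (`down` / `up` / `unchanged`, `NA` when unmeasured).
#' @export
target_expression_summary <- function(links, expr, p_max = 0.05) {
  stopifnot(all(c("gene_id", "fold_change", "p_adj") %in% names(expr)))
  genes <- unique(links$gene_id)
  genes <- genes[!is.na(genes)]
  out <- left_join(tibble(gene_id = genes), as_tibble(expr), by = "gene_id")
  out$in_expr <- !is.na(out$fold_change) & !is.na(out$p_adj)
  out$direction <- case_when(
    !out$in_expr ~ NA_character_,
    out$p_adj < p_max & out$fold_change < 1 ~ "down",
    out$p_adj < p_max & out$fold_change > 1 ~ "up",
    TRUE ~ "unchanged")
  out
}

#' Read RRBS-style per-CpG records
#'
#' TSV with columns `chrom`, `pos`, `coverage`, `beta`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_rrbs <- function(path) {
  r <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         pos = readr::col_integer(),
                         coverage = readr::col_integer(),
                         beta = readr::col_double()))
  if (any(r$beta < 0 | r$beta > 1, na.rm = TRUE)) {
    abort("beta values must be in [0, 1]")
  }
  r
}

#' Methylation histograms inside vs outside binding peaks
#'
#' The standard display of methylation / binding mutual exclusivity: beta
#' distributions for CpGs overlapping the peak set (red) and not (green).
#'
#' @param records Output of [partition_by_peaks()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_methylation_partition <- function(records, bins = 20) {
  stopifnot("in_peak" %in% names(records))
  d <- as_tibble(records)
  d$where <- ifelse(d$in_peak, "in peak", "outside peak")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, fill = .data$where)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6,
                            ggplot2::aes(y = ggplot2::after_stat(density))) +
    ggplot2::scale_fill_manual(values = c(`in peak` = "#c0392b",
                                          `outside peak` = "#27ae60")) +
    ggplot2::labs(x = "beta value", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}
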