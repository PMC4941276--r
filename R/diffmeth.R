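#' Differential-methylation calling thresholds
#'
#' Defaults reproduce the published calling rule: FDR-corrected p below 0.05
#' and a group beta-value difference (case minus control) strictly greater
#' than 0.15 in magnitude.
#'
#' @param q_max FDR-adjusted p-value ceiling (strict `<`).
#' @param delta_min Minimum |delta beta| (strict `>`).
#' @return A list of class `meth_thresholds`.
#' @export
meth_thresholds <- function(q_max = 0.05, delta_min = 0.15) {
  stopifnot(q_max > 0, q_max < 1, delta_min > 0, delta_min < 1)
  structure(list(q_max = q_max, delta_min = delta_min),
            class = "meth_thresholds")
}

#' Group beta-value difference
#'
#' Mean beta of the case group minus mean beta of the control group; the
#' effect size for array methylation. Missing values are dropped within each
#' group before averaging.
#'
#' @param case_betas,control_betas Numeric vectors of beta values in `[0, 1]`.
#' @return Delta beta, a value in `[-1, 1]`.
#' @examples
#' delta_beta(c(0.8, 0.8), c(0.6, 0.6)) # 0.2
#' @export
delta_beta <- function(case_betas, control_betas) {
  case_betas <- case_betas[!is.na(case_betas)]
  control_betas <- control_betas[!is.na(control_betas)]
  if (length(case_betas) == 0 || length(control_betas) == 0) {
    abort("empty group after missing-value removal")
  }
  if (any(case_betas < 0 | case_betas > 1) ||
      any(control_betas < 0 | control_betas > 1)) {
    abort("beta values must be in [0, 1]")
  }
  mean(case_betas) - mean(control_betas)
}

# Vectorised Welch two-sample t-test over matrix rows.
# Degenerate rows (both group variances zero) follow the package convention:
# equal constants -> p = 1, different constants -> p = 0.
.welch_rows <- function(x_case, x_ctrl) {
  n1 <- rowSums(!is.na(x_case))
  n2 <- rowSums(!is.na(x_ctrl))
  m1 <- rowMeans(x_case, na.rm = TRUE)
  m2 <- rowMeans(x_ctrl, na.rm = TRUE)
  v1 <- rowSums((x_case - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x_ctrl - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(stat), df)
  degen <- se2 == 0
  if (any(degen)) {
    same <- degen & (m1 == m2)
    stat[degen] <- ifelse(same[degen], 0, Inf * sign(m1 - m2)[degen])
    p[degen] <- ifelse(same[degen], 1, 0)
  }
  list(statistic = stat, p = p, delta = m1 - m2, n1 = n1, n2 = n2)
}

#' Per-probe two-group test on beta values
#'
#' Two-sided Welch two-sample t-test (default) or Wilcoxon rank-sum test on
#' the beta values of one probe. Degenerate zero-variance inputs follow a
#' documented convention: both groups constant and equal gives p = 1; constant
#' and different gives p = 0.
#'
#' @inheritParams delta_beta
#' @param test `"welch"` or `"wilcoxon"`.
#' @return A tibble with columns `statistic` and `p`.
#' @export
test_probe <- function(case_betas, control_betas,
                       test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  case_betas <- case_betas[!is.na(case_betas)]
  control_betas <- control_betas[!is.na(control_betas)]
  if (length(case_betas) < 2 || length(control_betas) < 2) {
    abort("need >= 2 observations per group")
  }
  if (test == "welch") {
    r <- .welch_rows(matrix(case_betas, nrow = 1),
                     matrix(control_betas, nrow = 1))
    tibble(statistic = r$statistic, p = r$p)
  } else {
    if (sd(case_betas) == 0 && sd(control_betas) == 0) {
      same <- mean(case_betas) == mean(control_betas)
      return(tibble(statistic = NA_real_, p = if (same) 1 else 0))
    }
    w <- suppressWarnings(wilcox.test(case_betas, control_betas))
    tibble(statistic = unname(w$statistic), p = w$p.value)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR control across one batch of p-values.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, order-preserving, with `q >= p`.
#' @export
adjust_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must be in [0, 1] and non-missing")
  }
  p.adjust(pvals, method = "BH")
}

#' Label probes as hyper-, hypo- or unmethylated-unchanged
#'
#' Applies the calling rule with strict inequalities: `hyper` iff
#' `q < q_max` and `delta_beta > delta_min`; `hypo` iff `q < q_max` and
#' `delta_beta < -delta_min`; otherwise `unchanged`.
#'
#' @param records A data frame with columns `q` and `delta_beta`.
#' @param thresholds A [meth_thresholds()] object.
#' @return `records` with a `label` factor column added.
#' @export
classify_probes <- function(records, thresholds = meth_thresholds()) {
  stopifnot(inherits(thresholds, "meth_thresholds"),
            all(c("q", "delta_beta") %in% names(records)))
  records <- as_tibble(records)
  records$label <- factor(
    case_when(
      records$q < thresholds$q_max &
        records$delta_beta > thresholds$delta_min ~ "hyper",
      records$q < thresholds$q_max &
        records$delta_beta < -thresholds$delta_min ~ "hypo",
      TRUE ~ "unchanged"),
    levels = c("hyper", "hypo", "unchanged"))
  records
}

#' Differential methylation between case and control groups
#'
#' Runs the per-probe test across a full beta matrix, applies
#' Benjamini-Hochberg FDR correction in one batch, computes delta beta
#' (case minus control) and labels each probe. Probes with fewer than two
#' observed values in either group are excluded from testing.
#'
#' @param betas A data frame with a `probe_id` column and one numeric column
#'   of beta values per sample.
#' @param samples A data frame with columns `sample_id` and `group`; `group`
#'   values must match `case` / `control`.
#' @param thresholds A [meth_thresholds()] object.
#' @param test Per-probe test, `"welch"` (default) or `"wilcoxon"`.
#' @param case,control The `group` values denoting cases and controls.
#' @return An object of class `meth_diff` with a `results` tibble
#'   (`probe_id`, `delta_beta`, `p`, `q`, `label`). Use [tidy()] for the
#'   table and [glance()] for call counts.
#' @export
diff_methylation <- function(betas, samples, thresholds = meth_thresholds(),
                             test = c("welch", "wilcoxon"),
                             case = "case", control = "control") {
  test <- match.arg(test)
  betas <- as_tibble(betas)
  samples <- as_tibble(samples)
  stopifnot("probe_id" %in% names(betas),
            all(c("sample_id", "group") %in% names(samples)))
  case_ids <- samples$sample_id[samples$group == case]
  ctrl_ids <- samples$sample_id[samples$group == control]
  if (length(case_ids) < 2 || length(ctrl_ids) < 2) {
    abort("need >= 2 samples per group")
  }
  missing_cols <- setdiff(c(case_ids, ctrl_ids), names(betas))
  if (length(missing_cols) > 0) {
    abort(paste0("samples absent from beta matrix: ",
                 paste(head(missing_cols, 5), collapse = ", ")))
  }
  x_case <- as.matrix(betas[, case_ids])
  x_ctrl <- as.matrix(betas[, ctrl_ids])
  rng <- range(c(x_case, x_ctrl), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) abort("beta values must be in [0, 1]")

  ok <- rowSums(!is.na(x_case)) >= 2 & rowSums(!is.na(x_ctrl)) >= 2
  n_dropped <- sum(!ok)
  probe_id <- betas$probe_id[ok]
  x_case <- x_case[ok, , drop = FALSE]
  x_ctrl <- x_ctrl[ok, , drop = FALSE]

  if (test == "welch") {
    w <- .welch_rows(x_case, x_ctrl)
    res <- tibble(probe_id = probe_id, delta_beta = w$delta, p = w$p)
  } else {
    p <- vapply(seq_along(probe_id), function(i) {
      test_probe(x_case[i, ], x_ctrl[i, ], test = "wilcoxon")$p
    }, numeric(1))
    res <- tibble(probe_id = probe_id,
                  delta_beta = rowMeans(x_case, na.rm = TRUE) -
                    rowMeans(x_ctrl, na.rm = TRUE),
                  p = p)
  }
  res$q <- adjust_fdr(res$p)
  res <- classify_probes(res, thresholds)
  structure(list(results = res, thresholds = thresholds, test = test,
                 n_case = length(case_ids), n_control = length(ctrl_ids),
                 n_dropped = n_dropped),
            class = "meth_diff")
}

#' @export
print.meth_diff <- function(x, ...) {
  cnt <- table(x$results$label)
  cat("<meth_diff> ", nrow(x$results), " probes tested (", x$test,
      " test), ", x$n_case, " case vs ", x$n_control, " control samples\n",
      sep = "")
  cat("  hyper: ", cnt[["hyper"]], "  hypo: ", cnt[["hypo"]],
      "  unchanged: ", cnt[["unchanged"]],
      "  (q < ", x$thresholds$q_max, ", |delta beta| > ",
      x$thresholds$delta_min, ")\n", sep = "")
  invisible(x)
}

#' @rdname diff_methylation
#' @param x A `meth_diff` object.
#' @param ... Unused.
#' @method tidy meth_diff
#' @export
tidy.meth_diff <- function(x, ...) x$results

#' @rdname diff_methylation
#' @method glance meth_diff
#' @export
glance.meth_diff <- function(x, ...) {
  cnt <- table(x$results$label)
  tibble(n_probes = nrow(x$results),
         n_hyper = unname(cnt[["hyper"]]),
         n_hypo = unname(cnt[["hypo"]]),
         n_unchanged = unname(cnt[["unchanged"]]),
         n_dropped = x$n_dropped,
         n_case = x$n_case, n_control = x$n_control,
         q_max = x$thresholds$q_max, delta_min = x$thresholds$delta_min)
}

#' Probe ids called in a given direction
#'
#' @param x A `meth_diff` object.
#' @param direction `"hyper"` or `"hypo"`.
#' @return Character vector of probe ids.
#' @export
called_probes <- function(x, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  stopifnot(inherits(x, "meth_diff"))
  x$results$probe_id[x$results$label == direction]
}

#' Five-number summaries of effect magnitudes in two cohorts
#'
#' Compares the distribution of |delta beta| (or signed delta beta) between
#' two cohorts over a shared probe subset, e.g. inflamed-vs-healthy against
#' tumor-vs-adjacent-normal.
#'
#' @param deltas_a,deltas_b Numeric vectors of delta-beta values.
#' @param names Labels for the two cohorts.
#' @return A tibble with one row per cohort: `cohort`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
magnitude_summary <- function(deltas_a, deltas_b,
                              names = c("cohort_a", "cohort_b")) {
  stopifnot(length(deltas_a) > 0, length(deltas_b) > 0, length(names) == 2)
  one <- function(v, nm) {
    q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    tibble(cohort = nm, n = length(v), min = q[1], q1 = q[2],
           median = q[3], q3 = q[4], max = q[5])
  }
  bind_rows(one(deltas_a, names[1]), one(deltas_b, names[2]))
}

#' Volcano-plot data and figure for a differential methylation result
#'
#' @param x A `meth_diff` object.
#' @param ... Unused.
#' @return A ggplot: delta beta on x, -log10(q) on y, coloured by call.
#' @method autoplot meth_diff
#' @export
autoplot.meth_diff <- function(x, ...) {
  d <- x$results
  d$neg_log10_q <- -log10(pmax(d$q, .Machine$double.xmin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_beta,
                                  y = .data$neg_log10_q,
                                  colour = .data$label)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(hyper = "#c0392b",
                                            hypo = "#27ae60",
                                            unchanged = "grey60")) +
    ggplot2::geom_vline(xintercept = c(-x$thresholds$delta_min,
                                       x$thresholds$delta_min),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "delta beta (case - control)",
                  y = expression(-log[10](q)), colour = NULL) +
    ggplot2::theme_minimal()
}
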