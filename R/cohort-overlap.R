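#' Upper-tail hypergeometric probability of a set overlap
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` shared probes when a set of size `n` is drawn from a
#' universe of `N` probes of which `K` belong to the other set. Computed via
#' the log-space tail of [stats::phyper()] so extreme tails (the published
#' overlaps reach p ~ 1e-197) do not underflow prematurely.
#'
#' @param k Observed overlap.
#' @param K Size of the other (cohort-B) set within the universe.
#' @param n Size of the drawn (cohort-A) set within the universe.
#' @param N Universe size.
#' @param log.p Return log probability.
#' @return Upper-tail p in `(0, 1]` (or its log).
#' @export
hypergeom_upper <- function(k, K, n, N, log.p = FALSE) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    abort("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE, log.p = log.p)
}

#' Directional overlap of differential probe sets between two cohorts
#'
#' Crosses the hyper/hypo calls of cohort A with those of cohort B over the
#' universe of probes tested in both cohorts, reporting for each of the four
#' direction pairs the overlap `k`, the proportion `k / nA`, and the
#' upper-tail hypergeometric p (enrichment of overlap; no correction across
#' the four cells, matching how such overlaps are conventionally reported).
#' Both tables must have been labeled with identical thresholds.
#'
#' @param diff_a,diff_b `meth_diff` objects or data frames with `probe_id`
#'   and `label` columns.
#' @param names Cohort labels for the output.
#' @return A tibble of class `cohort_overlap` with columns `a_label`,
#'   `b_label`, `n_universe`, `n_a`, `n_b`, `k`, `proportion`, `p_hyper`.
#' @export
directional_overlap <- function(diff_a, diff_b,
                                names = c("cohort_a", "cohort_b")) {
  tab_a <- if (inherits(diff_a, "meth_diff")) diff_a$results else
    as_tibble(diff_a)
  tab_b <- if (inherits(diff_b, "meth_diff")) diff_b$results else
    as_tibble(diff_b)
  stopifnot(all(c("probe_id", "label") %in% names(tab_a)),
            all(c("probe_id", "label") %in% names(tab_b)))
  universe <- intersect(tab_a$probe_id, tab_b$probe_id)
  if (length(universe) == 0) abort("empty probe universe across cohorts")
  N <- length(universe)
  a_sets <- lapply(c(hyper = "hyper", hypo = "hypo"), function(l) {
    intersect(tab_a$probe_id[tab_a$label == l], universe)
  })
  b_sets <- lapply(c(hyper = "hyper", hypo = "hypo"), function(l) {
    intersect(tab_b$probe_id[tab_b$label == l], universe)
  })
  rows <- list()
  for (la in names(a_sets)) {
    for (lb in names(b_sets)) {
      nA <- length(a_sets[[la]]); nB <- length(b_sets[[lb]])
      k <- length(intersect(a_sets[[la]], b_sets[[lb]]))
      rows[[paste(la, lb)]] <- tibble(
        a_label = la, b_label = lb, n_universe = N, n_a = nA, n_b = nB,
        k = k, proportion = if (nA > 0) k / nA else NA_real_,
        p_hyper = hypergeom_upper(k, K = nB, n = nA, N = N))
    }
  }
  out <- bind_rows(rows)
  attr(out, "cohorts") <- names
  class(out) <- unique(c("cohort_overlap", class(out)))
  out
}

#' @rdname directional_overlap
#' @param x A `cohort_overlap` table.
#' @param ... Unused.
#' @method tidy cohort_overlap
#' @export
tidy.cohort_overlap <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cohort_overlap")
  as_tibble(out)
}

#' @rdname directional_overlap
#' @method glance cohort_overlap
#' @export
glance.cohort_overlap <- function(x, ...) {
  same <- x$a_label == x$b_label
  tibble(n_universe = x$n_universe[1],
         min_p_same_direction = min(x$p_hyper[same]),
         min_p_cross_direction = min(x$p_hyper[!same]))
}

#' Overlap-proportion bar panel for a cohort-overlap result
#'
#' @param x A `cohort_overlap` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_overlap
#' @export
autoplot.cohort_overlap <- function(x, ...) {
  d <- tidy(x)
  d$cell <- paste0("A-", d$a_label, " : B-", d$b_label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$proportion,
                                  fill = .data$a_label == .data$b_label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c3e50",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "overlap / cohort-A set size") +
    ggplot2::theme_minimal()
}
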