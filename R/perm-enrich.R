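#' Count probes overlapping a feature set
#'
#' Number of probes in `probe_ids` whose manifest position falls inside at
#' least one interval of `features` (half-open, single-base overlap).
#'
#' @param probe_ids Character vector of probe ids.
#' @param manifest Probe manifest tibble (`probe_id`, `chrom`, `pos`).
#' @param features A `feature_set`.
#' @return Integer overlap count.
#' @export
observed_overlap <- function(probe_ids, manifest, features) {
  if (length(probe_ids) == 0) return(0L)
  idx <- match(probe_ids, manifest$probe_id)
  if (anyNA(idx)) {
    abort(paste0("probe id(s) not in manifest: ",
                 paste(head(probe_ids[is.na(idx)], 5), collapse = ", ")))
  }
  sum(position_overlaps(manifest[idx, c("chrom", "pos")], features))
}

#' Permutation null for a probe-set overlap count
#'
#' Builds the null distribution used throughout the enrichment analysis:
#' each replicate draws `k` distinct probes uniformly without replacement
#' from the full array manifest (the array background) and records how many
#' fall inside the feature set.
#'
#' @param k Size of the probe set being permuted.
#' @param manifest Probe manifest tibble.
#' @param features A `feature_set`.
#' @param n_perm Number of permutation replicates (default 1000).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Integer vector of `n_perm` overlap counts.
#' @export
permutation_null <- function(k, manifest, features, n_perm = 1000L,
                             seed = 1L) {
  n <- nrow(manifest)
  if (k > n) abort("k exceeds manifest size")
  if (n_perm < 100) abort("n_perm must be >= 100")
  hit <- position_overlaps(manifest[, c("chrom", "pos")], features)
  withr::with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(hit[sample.int(n, k)]),
           integer(1))
  })
}

#' Z-score and empirical p for an observed overlap against its null
#'
#' `z = (observed - mean(null)) / sd(null)` with the sample standard
#' deviation. The empirical p uses the add-one estimator so it is never zero:
#' for enrichment `(1 + #\{null >= observed\}) / (n_perm + 1)`, for depletion
#' the lower-tail analogue, and for `two_sided` twice the smaller one-sided p
#' capped at 1. Direction is called from the sign of z when the empirical p
#' is below `alpha`; with a degenerate null (zero sd) z is `NA`, direction is
#' `none` and `degenerate_null` is flagged.
#'
#' @param observed Observed overlap count.
#' @param null_counts Integer vector of permutation overlap counts
#'   (length >= 100).
#' @param alternative `"enrichment"`, `"depletion"` or `"two_sided"`.
#' @param alpha Empirical-p significance level for calling a direction.
#' @return One-row tibble: `observed`, `null_mean`, `null_sd`, `z`, `p_emp`,
#'   `direction`, `degenerate_null`.
#' @export
enrichment_z <- function(observed, null_counts,
                         alternative = c("two_sided", "enrichment",
                                         "depletion"),
                         alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (length(null_counts) < 100) abort("null_counts must have length >= 100")
  n_perm <- length(null_counts)
  mu <- mean(null_counts)
  s <- sd(null_counts)
  p_up <- (1 + sum(null_counts >= observed)) / (n_perm + 1)
  p_dn <- (1 + sum(null_counts <= observed)) / (n_perm + 1)
  p_emp <- switch(alternative,
                  enrichment = p_up,
                  depletion = p_dn,
                  two_sided = min(1, 2 * min(p_up, p_dn)))
  if (s == 0) {
    return(tibble(observed = observed, null_mean = mu, null_sd = s,
                  z = NA_real_, p_emp = p_emp, direction = "none",
                  degenerate_null = TRUE))
  }
  z <- (observed - mu) / s
  direction <- if (p_emp < alpha && z > 0) "enriched"
               else if (p_emp < alpha && z < 0) "depleted"
               else "none"
  tibble(observed = observed, null_mean = mu, null_sd = s, z = z,
         p_emp = p_emp, direction = direction, degenerate_null = FALSE)
}

#' Enrichment report: probe sets crossed with feature sets
#'
#' Runs the full permutation enrichment analysis: for each probe set
#' (typically the hyper- and hypomethylated calls) against each feature set
#' (peaks for one mark in one cell line), the observed overlap is compared
#' with `n_perm` equal-sized random probe sets drawn from the array
#' background. Nulls are resampled independently per (probe set, feature
#' set) cell with a seed derived from `seed` and the cell index, so the
#' table is bit-reproducible and cells could be computed in parallel.
#'
#' @param probe_sets Named list of character vectors of probe ids, e.g.
#'   `list(hyper = ..., hypo = ...)`.
#' @param feature_sets A `feature_set` or list of them.
#' @param manifest Probe manifest tibble.
#' @inheritParams permutation_null
#' @inheritParams enrichment_z
#' @return A tibble of class `meth_enrichment`: one row per probe set x
#'   feature set with `probe_set`, `feature`, `n_probes`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_emp`, `direction`.
#' @export
enrich_report <- function(probe_sets, feature_sets, manifest,
                          n_perm = 1000L, seed = 1L,
                          alternative = "two_sided", alpha = 0.05) {
  if (inherits(feature_sets, "feature_set")) {
    feature_sets <- list(feature_sets)
  }
  if (is.null(names(probe_sets)) || any(!nzchar(names(probe_sets)))) {
    abort("probe_sets must be a named list")
  }
  cell <- 0L
  rows <- list()
  for (j in seq_along(feature_sets)) {
    fs <- feature_sets[[j]]
    for (i in seq_along(probe_sets)) {
      cell <- cell + 1L
      ids <- probe_sets[[i]]
      obs <- observed_overlap(ids, manifest, fs)
      null <- permutation_null(length(ids), manifest, fs, n_perm = n_perm,
                               seed = seed + cell)
      r <- enrichment_z(obs, null, alternative = alternative, alpha = alpha)
      r <- mutate(r, probe_set = names(probe_sets)[i], feature = set_name(fs),
                  n_probes = length(ids), .before = 1)
      rows[[cell]] <- r
    }
  }
  out <- bind_rows(rows)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- unique(c("meth_enrichment", class(out)))
  out
}

#' @rdname enrich_report
#' @param x A `meth_enrichment` table.
#' @param ... Unused.
#' @method tidy meth_enrichment
#' @export
tidy.meth_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "meth_enrichment")
  as_tibble(out)
}

#' @rdname enrich_report
#' @method glance meth_enrichment
#' @export
glance.meth_enrichment <- function(x, ...) {
  tibble(n_cells = nrow(x),
         n_enriched = sum(x$direction == "enriched"),
         n_depleted = sum(x$direction == "depleted"),
         n_perm = attr(x, "n_perm"))
}

#' Z-score panel for an enrichment report
#'
#' Mirrors the field's standard display: one point per feature set, Z-score
#' on the y axis, enriched cells in red and depleted in green, faceted by
#' probe set.
#'
#' @param x A `meth_enrichment` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meth_enrichment
#' @export
autoplot.meth_enrichment <- function(x, ...) {
  d <- tidy(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$z,
                                  colour = .data$direction)) +
    ggplot2::geom_point(shape = 18, size = 3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(enriched = "#c0392b",
                                            depleted = "#27ae60",
                                            none = "grey50")) +
    ggplot2::facet_wrap(~probe_set) +
    ggplot2::labs(x = NULL, y = "Z-score", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
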