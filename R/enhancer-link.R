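#' Configuration for enhancer-to-target linking
#'
#' Defaults reproduce the published linking rule: candidate DHS within
#' +/- 500 kb of the anchor enhancer, pairwise Pearson correlation of DNase
#' signal across cell lines with `r^2 >= 0.7`, and target promoters defined
#' as +/- 2.5 kb around a TSS.
#'
#' @param window Candidate search half-window around the anchor, bp.
#' @param r2_min Minimum squared Pearson correlation to emit a link.
#' @param promoter_halfwidth Promoter half-width around the TSS, bp.
#' @param log_signal Correlate `log1p(signal)` instead of raw signal
#'   (DNase signal is heavy-tailed; off by default).
#' @return A list of class `link_config`.
#' @export
link_config <- function(window = 500000L, r2_min = 0.7,
                        promoter_halfwidth = 2500L, log_signal = FALSE) {
  stopifnot(window > 0, r2_min > 0, r2_min <= 1, promoter_halfwidth > 0)
  structure(list(window = as.integer(window), r2_min = r2_min,
                 promoter_halfwidth = as.integer(promoter_halfwidth),
                 log_signal = isTRUE(log_signal)),
            class = "link_config")
}

#' Call putative enhancers: DHS without the promoter mark
#'
#' A putative enhancer is a DNase hypersensitive site with zero base-pair
#' overlap with any H3K4me3 (promoter-associated) peak. The output is always
#' a subset of the input DHS set, so the operation is idempotent.
#'
#' @param dhs A `feature_set` of DHS intervals.
#' @param h3k4me3 A `feature_set` of H3K4me3 peaks.
#' @return A `feature_set` of the retained DHS.
#' @export
call_putative_enhancers <- function(dhs, h3k4me3) {
  if (nrow(dhs) == 0 || nrow(h3k4me3) == 0) {
    return(feature_set(dhs, name = paste0(set_name(dhs), "_noH3K4me3")))
  }
  keep <- rep(TRUE, nrow(dhs))
  d <- .ranges_by_chrom(dhs$chrom, dhs$start, dhs$end)
  h <- .ranges_by_chrom(h3k4me3$chrom, h3k4me3$start, h3k4me3$end)
  for (chr in intersect(names(d), names(h))) {
    hit <- IRanges::countOverlaps(d[[chr]]$ir, h[[chr]]$ir) > 0
    keep[d[[chr]]$idx[hit]] <- FALSE
  }
  feature_set(dhs[keep, , drop = FALSE],
              name = paste0(set_name(dhs), "_noH3K4me3"))
}

#' Enhancers containing at least one hypermethylated probe
#'
#' Intersects an enhancer set with the positions of hypermethylated probes;
#' an enhancer is retained once however many probes it contains.
#'
#' @param enhancers A `feature_set`.
#' @param hyper_probes Character vector of hypermethylated probe ids.
#' @param manifest Probe manifest tibble.
#' @return A `feature_set` of hypermethylated enhancers.
#' @export
hypermethylated_enhancers <- function(enhancers, hyper_probes, manifest) {
  idx <- match(hyper_probes, manifest$probe_id)
  if (anyNA(idx)) abort("hyper probe id(s) not in manifest")
  keep <- rep(FALSE, nrow(enhancers))
  if (nrow(enhancers) > 0 && length(idx) > 0) {
    pos <- manifest[idx, ]
    e <- .ranges_by_chrom(enhancers$chrom, enhancers$start, enhancers$end)
    p <- .ranges_by_chrom(pos$chrom, pos$pos, pos$pos + 1L)
    for (chr in intersect(names(e), names(p))) {
      hit <- IRanges::countOverlaps(e[[chr]]$ir, p[[chr]]$ir) > 0
      keep[e[[chr]]$idx[hit]] <- TRUE
    }
  }
  feature_set(enhancers[keep, , drop = FALSE],
              name = paste0(set_name(enhancers), "_hypermeth"))
}

#' Pearson correlation of two signal vectors
#'
#' Standard product-moment correlation; returns `NA` when either vector has
#' zero variance (such candidate pairs are excluded from linking).
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return `r` in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length vectors of length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

.site_mid <- function(start, end) (start + end) / 2

# Nearest TSS within hw of a midpoint; ties broken by lexicographic gene_id.
.assign_gene <- function(chrom, mid, genes, hw) {
  cand <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  d <- abs(cand$tss - mid)
  ok <- d <= hw
  if (!any(ok)) return(NA_character_)
  cand <- cand[ok, , drop = FALSE]
  d <- d[ok]
  best <- which(d == min(d))
  sort(cand$gene_id[best])[1]
}

#' Link one enhancer to candidate target DHS by signal correlation
#'
#' For one anchor enhancer, considers every DHS site in the signal matrix on
#' the same chromosome whose midpoint lies within `window` bp of the anchor
#' midpoint (excluding the anchor itself), computes the Pearson correlation
#' of DNase signal across cell lines, and emits links with
#' `r^2 >= r2_min`, sorted by descending `r^2`. A link is annotated with a
#' gene when the target midpoint lies within `promoter_halfwidth` of a TSS
#' (nearest TSS wins; ties broken by gene id).
#'
#' The anchor is matched to the signal-matrix site whose interval overlaps
#' it most; an anchor overlapping no site is an error (the enhancer is
#' itself expected to be a DHS).
#'
#' @param anchor One-row data frame (`chrom`, `start`, `end`) or a
#'   `feature_set` row.
#' @param signal Signal matrix: tibble with `chrom`, `start`, `end` plus one
#'   numeric column per cell line (>= 8 cell lines).
#' @param genes Gene-model tibble ([gene_models()]).
#' @param config A [link_config()].
#' @return Tibble of links: `enh_chrom`, `enh_start`, `enh_end`,
#'   `dhs_chrom`, `dhs_start`, `dhs_end`, `r`, `r2`, `distance`, `gene_id`.
#' @export
link_enhancer_targets <- function(anchor, signal, genes,
                                  config = link_config()) {
  anchor <- as_tibble(anchor)
  stopifnot(nrow(anchor) == 1,
            all(c("chrom", "start", "end") %in% names(anchor)))
  cell_cols <- setdiff(names(signal), c("chrom", "start", "end"))
  if (length(cell_cols) < 8) {
    abort("signal matrix needs >= 8 cell-line columns")
  }
  same <- which(signal$chrom == anchor$chrom)
  ov <- pmin(signal$end[same], anchor$end) -
    pmax(signal$start[same], anchor$start)
  if (length(same) == 0 || all(ov <= 0)) {
    abort("anchor does not overlap any signal-matrix site")
  }
  anchor_idx <- same[which.max(ov)]
  sig_mat <- as.matrix(signal[, cell_cols])
  if (config$log_signal) sig_mat <- log1p(sig_mat)
  if (any(sig_mat < 0)) abort("signal values must be non-negative")

  a_mid <- .site_mid(signal$start[anchor_idx], signal$end[anchor_idx])
  mids <- .site_mid(signal$start, signal$end)
  cand <- setdiff(which(signal$chrom == anchor$chrom &
                          abs(mids - a_mid) <= config$window), anchor_idx)
  if (length(cand) == 0) return(.empty_links())
  a_sig <- sig_mat[anchor_idx, ]
  r <- vapply(cand, function(i) {
    if (sd(a_sig) == 0 || sd(sig_mat[i, ]) == 0) NA_real_
    else cor(a_sig, sig_mat[i, ])
  }, numeric(1))
  keep <- !is.na(r) & r^2 >= config$r2_min
  cand <- cand[keep]; r <- r[keep]
  if (length(cand) == 0) return(.empty_links())
  gene_id <- vapply(cand, function(i) {
    .assign_gene(signal$chrom[i], mids[i], genes, config$promoter_halfwidth)
  }, character(1))
  out <- tibble(
    enh_chrom = anchor$chrom, enh_start = anchor$start,
    enh_end = anchor$end,
    dhs_chrom = signal$chrom[cand], dhs_start = signal$start[cand],
    dhs_end = signal$end[cand],
    r = r, r2 = r^2, distance = abs(mids[cand] - a_mid),
    gene_id = gene_id)
  arrange(out, dplyr::desc(.data$r2))
}

.empty_links <- function() {
  tibble(enh_chrom = character(), enh_start = integer(),
         enh_end = integer(), dhs_chrom = character(),
         dhs_start = integer(), dhs_end = integer(), r = numeric(),
         r2 = numeric(), distance = numeric(), gene_id = character())
}

#' Link every enhancer in a set to its targets
#'
#' Applies [link_enhancer_targets()] to each interval of an enhancer set and
#' binds the results. Enhancers that match no signal-matrix site are skipped
#' with a warning rather than aborting the batch.
#'
#' @param enhancers A `feature_set` of (hypermethylated) enhancers.
#' @inheritParams link_enhancer_targets
#' @return Tibble of links across all anchors.
#' @export
link_enhancers <- function(enhancers, signal, genes,
                           config = link_config()) {
  rows <- vector("list", nrow(enhancers))
  n_skipped <- 0L
  for (i in seq_len(nrow(enhancers))) {
    rows[[i]] <- tryCatch(
      link_enhancer_targets(enhancers[i, ], signal, genes, config),
      error = function(e) {
        n_skipped <<- n_skipped + 1L
        NULL
      })
  }
  if (n_skipped > 0) {
    warn(paste0(n_skipped, " enhancer(s) matched no signal-matrix site ",
                "and were skipped"))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) .empty_links() else out
}

#' Read / write a DHS signal matrix
#'
#' TSV with columns `chrom`, `start`, `end` then one numeric column per cell
#' line.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_signal_matrix <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(s)))
  s$start <- as.integer(s$start); s$end <- as.integer(s$end)
  s
}

#' @rdname read_signal_matrix
#' @param signal Signal-matrix tibble.
#' @export
write_signal_matrix <- function(signal, path) {
  readr::write_tsv(signal, path)
  invisible(path)
}
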