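#' Run the full analysis pipeline on a study bundle
#'
#' Orchestrates the stages end to end: differential methylation calling,
#' permutation enrichment of the hyper/hypo calls at each feature set,
#' putative-enhancer calling (DHS minus H3K4me3) and hypermethylated-
#' enhancer linking to target promoters, expression annotation of linked
#' genes, directional cross-cohort overlap (when a second cohort is
#' present), and the RRBS peak-partition Kolmogorov-Smirnov analysis.
#' When the bundle carries planted ground truth a recovery report is added.
#'
#' @param bundle A [gen_synthetic_study()] bundle, or any list with the
#'   same elements built from user data (`manifest`, `betas`, `samples`,
#'   `feature_sets`, `signal`, `dhs_set`, `h3k4me3`, `genes`, `expression`,
#'   `rrbs`, `rrbs_peaks`; optionally `betas_b`, `samples_b`, `truth`).
#' @param thresholds A [meth_thresholds()].
#' @param n_perm Permutations per enrichment cell.
#' @param seed Seed for the permutation stage.
#' @param link_cfg A [link_config()].
#' @param outdir Optional directory; when given, every stage output is
#'   written as TSV and the provenance record as JSON.
#' @return A list of class `inflamethyl_run` with elements `diffmeth`,
#'   `enrichment`, `enhancers`, `links`, `target_expression`, `overlap`
#'   (or `NULL`), `rrbs_ks`, `recovery` (or `NULL`) and `provenance`.
#' @export
run_pipeline <- function(bundle, thresholds = meth_thresholds(),
                         n_perm = 1000L, seed = 1L,
                         link_cfg = link_config(), outdir = NULL) {
  required <- c("manifest", "betas", "samples", "feature_sets", "signal",
                "dhs_set", "h3k4me3", "genes", "expression", "rrbs",
                "rrbs_peaks")
  missing_el <- setdiff(required, names(bundle))
  if (length(missing_el) > 0) {
    abort(paste0("bundle is missing element(s): ",
                 paste(missing_el, collapse = ", ")))
  }

  dm <- .stage("diffmeth", diff_methylation(bundle$betas, bundle$samples,
                                            thresholds))
  hyper <- called_probes(dm, "hyper")
  hypo <- called_probes(dm, "hypo")

  enr <- .stage("perm_enrich", enrich_report(
    list(hyper = hyper, hypo = hypo), bundle$feature_sets,
    bundle$manifest, n_perm = n_perm, seed = seed))

  putative <- .stage("enhancer_link",
                     call_putative_enhancers(bundle$dhs_set, bundle$h3k4me3))
  hyp_enh <- hypermethylated_enhancers(putative, hyper, bundle$manifest)
  links <- suppressWarnings(
    link_enhancers(hyp_enh, bundle$signal, bundle$genes, link_cfg))
  tes <- target_expression_summary(links, bundle$expression)

  overlap <- NULL
  if (!is.null(bundle$betas_b)) {
    dm_b <- .stage("cohort_overlap",
                   diff_methylation(bundle$betas_b, bundle$samples_b,
                                    thresholds))
    overlap <- directional_overlap(dm, dm_b)
  }

  rrbs <- .stage("methyl_context_stats",
                 filter_coverage(bundle$rrbs, min_cov = 5L))
  rrbs <- partition_by_peaks(rrbs, bundle$rrbs_peaks)
  rrbs_ks <- if (sum(rrbs$in_peak) > 0 && sum(!rrbs$in_peak) > 0) {
    ks_two_sample(rrbs$beta[rrbs$in_peak], rrbs$beta[!rrbs$in_peak])
  } else NULL

  recovery <- NULL
  if (!is.null(bundle$truth)) {
    recovery <- .recovery_report(bundle$truth, hyper, hypo, enr, links, tes)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("inflamethyl")),
    config_hash = rlang::hash(bundle$config),
    seed = seed, n_perm = n_perm,
    thresholds = unclass(thresholds), link_config = unclass(link_cfg),
    stage_rows = list(diffmeth = nrow(dm$results), enrichment = nrow(enr),
                      putative_enhancers = nrow(putative),
                      hypermethylated_enhancers = nrow(hyp_enh),
                      links = nrow(links),
                      overlap = if (is.null(overlap)) 0L else nrow(overlap),
                      rrbs = nrow(rrbs)))

  run <- structure(list(diffmeth = dm, enrichment = enr,
                        enhancers = hyp_enh, links = links,
                        target_expression = tes, overlap = overlap,
                        rrbs_ks = rrbs_ks, recovery = recovery,
                        provenance = provenance),
                   class = "inflamethyl_run")
  if (!is.null(outdir)) .write_run(run, outdir)
  run
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

.recovery_report <- function(truth, hyper, hypo, enr, links, tes) {
  tp <- length(intersect(hyper, truth$hyper_probes)) +
    length(intersect(hypo, truth$hypo_probes))
  n_planted <- length(truth$hyper_probes) + length(truth$hypo_probes)
  n_called <- length(hyper) + length(hypo)
  enr_tbl <- tidy(enr)
  planted_cells <- enr_tbl$feature %in% truth$enriched_features &
    enr_tbl$probe_set == "hyper"
  link_key <- paste(links$enh_start, links$gene_id)
  planted_key <- paste(truth$links$enh_start, truth$links$gene_id)
  down <- tes$direction[tes$gene_id %in% truth$down_genes]
  list(diffmeth_sensitivity = if (n_planted > 0) tp / n_planted else NA,
       diffmeth_precision = if (n_called > 0) tp / n_called else NA,
       enrichment_min_z_planted = if (any(planted_cells))
         min(enr_tbl$z[planted_cells]) else NA,
       link_sensitivity = if (nrow(truth$links) > 0)
         mean(planted_key %in% link_key) else NA,
       linked_targets_down_fraction = if (length(down) > 0)
         mean(down == "down", na.rm = TRUE) else NA)
}

.write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$diffmeth$results, file.path(outdir, "diffmeth.tsv"))
  readr::write_tsv(tidy(run$enrichment), file.path(outdir, "enrichment.tsv"))
  readr::write_tsv(as_tibble(run$enhancers),
                   file.path(outdir, "hypermethylated_enhancers.tsv"))
  readr::write_tsv(run$links, file.path(outdir, "links.tsv"))
  readr::write_tsv(run$target_expression,
                   file.path(outdir, "target_expression.tsv"))
  if (!is.null(run$overlap)) {
    readr::write_tsv(tidy(run$overlap), file.path(outdir, "overlap.tsv"))
  }
  jsonlite::write_json(c(run$provenance,
                         list(recovery = run$recovery,
                              rrbs_ks = run$rrbs_ks)),
                       file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.inflamethyl_run <- function(x, ...) {
  cat("<inflamethyl_run>\n")
  print(x$diffmeth)
  cat("  enrichment cells: ", nrow(x$enrichment),
      " (", sum(x$enrichment$direction == "enriched"), " enriched, ",
      sum(x$enrichment$direction == "depleted"), " depleted)\n", sep = "")
  cat("  hypermethylated enhancers: ", nrow(x$enhancers),
      "; links emitted: ", nrow(x$links), "\n", sep = "")
  if (!is.null(x$overlap)) {
    same <- x$overlap$a_label == x$overlap$b_label
    cat("  cross-cohort overlap: min same-direction p = ",
        format(min(x$overlap$p_hyper[same]), digits = 3), "\n", sep = "")
  }
  if (!is.null(x$rrbs_ks)) {
    cat("  RRBS peak-partition KS: D = ",
        format(x$rrbs_ks$D, digits = 3), ", p = ",
        format(x$rrbs_ks$p, digits = 3), "\n", sep = "")
  }
  if (!is.null(x$recovery)) {
    cat("  truth recovery: sensitivity ",
        format(x$recovery$diffmeth_sensitivity, digits = 3),
        ", precision ", format(x$recovery$diffmeth_precision, digits = 3),
        ", link sensitivity ",
        format(x$recovery$link_sensitivity, digits = 3), "\n", sep = "")
  }
  invisible(x)
}
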