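#' Configuration of the synthetic study generator
#'
#' Defaults emulate the statistical structure of the study design the
#' pipeline targets: a 450K-style array of `n_probes` CpGs compared between
#' 19 inflamed and 23 healthy samples; planted differential probes with a
#' delta-beta effect of 0.25 on Beta-distributed noise; peak sets
#' over-representing planted hyper probes 5-fold over a 10% base rate;
#' 50 planted enhancer-promoter pairs (true signal correlation ~0.9 across
#' 100 cell lines) among 500 independent decoy DHS; and RRBS records whose
#' methylation is suppressed inside looping-factor binding peaks.
#'
#' @param seed Master seed; every generator derives its stream from it.
#' @param n_probes Number of array probes.
#' @param genome_length Length of the single synthetic chromosome, bp.
#' @param n_case,n_control Samples per group.
#' @param frac_hyper,frac_hypo Fractions of probes planted as hyper-/
#'   hypomethylated in cases.
#' @param effect_delta Planted delta beta.
#' @param beta_concentration Beta-noise concentration (mean/concentration
#'   parameterisation; higher is less noisy).
#' @param n_cell_lines Cell lines in the DHS signal matrix.
#' @param n_planted_links Planted enhancer-promoter pairs.
#' @param n_decoy_dhs Decoy DHS sites with independent signal.
#' @param link_r Target Pearson correlation of planted pairs.
#' @param feature_base_rate Per-probe coverage probability of a feature set.
#' @param enrichment_fold Coverage multiplier for planted hyper probes in
#'   "enriched" feature sets.
#' @param n_enriched_features,n_null_features Feature sets of each kind.
#' @param exclusivity_strength In `[0, 1]`: how strongly RRBS methylation is
#'   suppressed inside binding peaks (0 = no effect, 1 = full mutual
#'   exclusivity).
#' @param n_rrbs RRBS CpG records.
#' @param low_coverage_frac Fraction of RRBS records with coverage below 5,
#'   to exercise the coverage filter.
#' @param n_cgi,n_genes CpG islands and gene models on the array chromosome.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_probes = 10000L,
                         genome_length = 20000000L,
                         n_case = 19L, n_control = 23L,
                         frac_hyper = 0.05, frac_hypo = 0.05,
                         effect_delta = 0.25, beta_concentration = 50,
                         n_cell_lines = 100L, n_planted_links = 50L,
                         n_decoy_dhs = 500L, link_r = 0.9,
                         feature_base_rate = 0.1, enrichment_fold = 5,
                         n_enriched_features = 2L, n_null_features = 2L,
                         exclusivity_strength = 1, n_rrbs = 10000L,
                         low_coverage_frac = 0.2,
                         n_cgi = 150L, n_genes = 60L) {
  cfg <- list(seed = as.integer(seed), n_probes = as.integer(n_probes),
              genome_length = as.integer(genome_length),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              frac_hyper = frac_hyper, frac_hypo = frac_hypo,
              effect_delta = effect_delta,
              beta_concentration = beta_concentration,
              n_cell_lines = as.integer(n_cell_lines),
              n_planted_links = as.integer(n_planted_links),
              n_decoy_dhs = as.integer(n_decoy_dhs), link_r = link_r,
              feature_base_rate = feature_base_rate,
              enrichment_fold = enrichment_fold,
              n_enriched_features = as.integer(n_enriched_features),
              n_null_features = as.integer(n_null_features),
              exclusivity_strength = exclusivity_strength,
              n_rrbs = as.integer(n_rrbs),
              low_coverage_frac = low_coverage_frac,
              n_cgi = as.integer(n_cgi), n_genes = as.integer(n_genes))
  with(cfg, {
    stopifnot(n_probes > 0, genome_length > n_probes,
              n_case >= 2, n_control >= 2,
              frac_hyper >= 0, frac_hyper <= 1,
              frac_hypo >= 0, frac_hypo <= 1, frac_hyper + frac_hypo <= 1,
              effect_delta >= 0, effect_delta < 1,
              beta_concentration > 2, n_cell_lines >= 8,
              link_r > 0, link_r < 1,
              feature_base_rate > 0, feature_base_rate < 1,
              enrichment_fold >= 1, exclusivity_strength >= 0,
              exclusivity_strength <= 1,
              low_coverage_frac >= 0, low_coverage_frac < 1)
    if (feature_base_rate * enrichment_fold > 1) {
      abort("infeasible coverage: feature_base_rate * enrichment_fold > 1")
    }
  })
  structure(cfg, class = "synth_config")
}

#' Generate a probe manifest with CGI and gene annotation context
#'
#' Places probes at uniformly random distinct positions on one synthetic
#' chromosome, scatters CpG islands and gene models so that all CGI
#' contexts (island / shore / shelf / open sea) and gene contexts
#' (promoter / exon / intron / intergenic) occur, and annotates every
#' probe. Deterministic given the configuration seed.
#'
#' @param config A [synth_config()].
#' @return List with `manifest` (tibble `probe_id`, `chrom`, `pos`,
#'   `cgi_context`, `gene_context`), `cgi` (`feature_set`) and `genes`
#'   (gene-model tibble).
#' @export
gen_manifest <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    chrom <- "chr1"
    pos <- sort(sample.int(config$genome_length - 1L, config$n_probes))
    manifest <- tibble(
      probe_id = sprintf("cg%07d", seq_len(config$n_probes)),
      chrom = chrom, pos = as.integer(pos))
    cgi_start <- sort(sample.int(config$genome_length - 2000L, config$n_cgi))
    cgi_width <- as.integer(round(runif(config$n_cgi, 500, 1500)))
    cgi <- feature_set(tibble(chrom = chrom, start = cgi_start,
                              end = cgi_start + cgi_width), name = "cgi")
    genes <- .gen_random_genes(config$n_genes, chrom,
                               config$genome_length, prefix = "GENE")
  })
  manifest$cgi_context <- annotate_cgi_context(manifest, cgi)
  manifest$gene_context <- annotate_gene_context(manifest, genes)
  list(manifest = manifest, cgi = cgi, genes = genes)
}

# Random gene models: 2-5 exons, 200-500 bp each, 0.5-2 kb introns,
# strand-appropriate TSS at the 5' end.
.gen_random_genes <- function(n, chrom, genome_length, prefix = "GENE") {
  gene_id <- character(n); strand <- character(n); tss <- integer(n)
  ex_s <- vector("list", n); ex_e <- vector("list", n)
  for (i in seq_len(n)) {
    n_ex <- sample(2:5, 1)
    widths <- as.integer(round(runif(n_ex, 200, 500)))
    gaps <- as.integer(round(runif(n_ex - 1, 500, 2000)))
    span <- sum(widths) + sum(gaps)
    left <- sample.int(genome_length - span - 1L, 1)
    starts <- left + c(0L, cumsum(widths[-n_ex] + gaps))
    ends <- starts + widths
    strand[i] <- sample(c("+", "-"), 1)
    tss[i] <- if (strand[i] == "+") starts[1] else ends[n_ex] - 1L
    gene_id[i] <- sprintf("%s%04d", prefix, i)
    ex_s[[i]] <- starts; ex_e[[i]] <- ends
  }
  gene_models(gene_id, rep(chrom, n), strand, tss, ex_s, ex_e)
}

#' Plant the differential-probe ground truth
#'
#' Samples disjoint hyper- and hypomethylated probe sets from the manifest.
#'
#' @param manifest Probe manifest tibble.
#' @param config A [synth_config()].
#' @return List of class `truth_set` with `hyper_probes`, `hypo_probes`
#'   (character vectors); later generators add `enriched_features`, `links`
#'   and `down_genes`.
#' @export
plant_truth <- function(manifest, config) {
  n_hyper <- round(config$frac_hyper * config$n_probes)
  n_hypo <- round(config$frac_hypo * config$n_probes)
  withr::with_seed(config$seed + 1L, {
    picked <- sample(manifest$probe_id, n_hyper + n_hypo)
  })
  structure(list(hyper_probes = picked[seq_len(n_hyper)],
                 hypo_probes = picked[n_hyper + seq_len(n_hypo)]),
            class = "truth_set")
}

#' Generate a beta-value matrix with planted group effects
#'
#' Unplanted probes share a probe-specific baseline mean drawn from a
#' bimodal distribution on `[0, 1]` (the characteristic two-peaked shape of
#' array methylation); per-sample values are Beta-distributed around the
#' group mean with the configured concentration. Planted hyper probes draw
#' their baseline from the unmethylated mode and gain `effect_delta` in
#' cases; planted hypo probes draw from the methylated mode and lose it
#' (methylation gains occur at normally-unmethylated CpGs, losses at
#' methylated ones, so the planted effect is realised without truncation).
#' Any mean still outside `[0.005, 0.995]` is clipped and counted. Sample
#' column order is randomized.
#'
#' @param manifest Probe manifest tibble.
#' @param truth A [plant_truth()] result.
#' @param config A [synth_config()].
#' @param seed Stream seed (defaults to a stream derived from the config
#'   seed; override to generate an independent cohort).
#' @return List with `betas` (tibble `probe_id` + sample columns),
#'   `samples` (tibble `sample_id`, `group`), and `n_clipped`.
#' @export
gen_beta_matrix <- function(manifest, truth, config,
                            seed = config$seed + 2L) {
  n <- nrow(manifest)
  conc <- config$beta_concentration
  withr::with_seed(seed, {
    high_mode <- rbinom(n, 1, 0.5) == 1
    base <- ifelse(high_mode, rbeta(n, 8, 2), rbeta(n, 2, 8))
    is_hyper <- manifest$probe_id %in% truth$hyper_probes
    is_hypo <- manifest$probe_id %in% truth$hypo_probes
    base[is_hyper] <- rbeta(sum(is_hyper), 2, 8)
    base[is_hypo] <- rbeta(sum(is_hypo), 8, 2)
    mu_case <- base + config$effect_delta * is_hyper -
      config$effect_delta * is_hypo
    mu_ctrl <- base
    n_clipped <- sum(mu_case < 0.005 | mu_case > 0.995 |
                       mu_ctrl < 0.005 | mu_ctrl > 0.995)
    mu_case <- pmin(pmax(mu_case, 0.005), 0.995)
    mu_ctrl <- pmin(pmax(mu_ctrl, 0.005), 0.995)
    draw <- function(mu, k) {
      matrix(rbeta(n * k, rep(mu * conc, k), rep((1 - mu) * conc, k)),
             nrow = n, ncol = k)
    }
    x_case <- draw(mu_case, config$n_case)
    x_ctrl <- draw(mu_ctrl, config$n_control)
    sample_id <- c(sprintf("case_%02d", seq_len(config$n_case)),
                   sprintf("ctrl_%02d", seq_len(config$n_control)))
    group <- rep(c("case", "control"), c(config$n_case, config$n_control))
    ord <- sample(length(sample_id))
  })
  values <- cbind(x_case, x_ctrl)[, ord, drop = FALSE]
  betas <- as_tibble(as.data.frame(values))
  names(betas) <- sample_id[ord]
  betas <- mutate(betas, probe_id = manifest$probe_id, .before = 1)
  list(betas = betas,
       samples = tibble(sample_id = sample_id[ord], group = group[ord]),
       n_clipped = n_clipped)
}

#' Generate feature sets with planted enrichment among hyper probes
#'
#' Each "enriched" set covers background probes with probability
#' `feature_base_rate` but planted hyper probes with probability
#' `feature_base_rate * enrichment_fold`; "null" sets cover all probes at
#' the base rate. Covered probes are wrapped in small intervals which are
#' merged so intervals never overlap within a set.
#'
#' @inheritParams gen_beta_matrix
#' @param halfwidth Interval half-width around a covered probe, bp.
#' @return Named list of `feature_set`s (`enriched_*`, `null_*`).
#' @export
gen_feature_sets <- function(manifest, truth, config, halfwidth = 25L) {
  rate <- config$feature_base_rate
  fold <- config$enrichment_fold
  if (rate * fold > 1) abort("infeasible coverage: rate * fold > 1")
  is_hyper <- manifest$probe_id %in% truth$hyper_probes
  nm <- c(sprintf("enriched_%d", seq_len(config$n_enriched_features)),
          sprintf("null_%d", seq_len(config$n_null_features)))
  out <- withr::with_seed(config$seed + 3L, {
    lapply(seq_along(nm), function(j) {
      p <- if (grepl("^enriched", nm[j])) {
        ifelse(is_hyper, rate * fold, rate)
      } else rep(rate, nrow(manifest))
      covered <- runif(nrow(manifest)) < p
      pos <- manifest$pos[covered]
      ir <- IRanges::reduce(IRanges::IRanges(
        start = pmax(pos - halfwidth, 0L) + 1L, end = pos + halfwidth + 1L))
      feature_set(tibble(chrom = manifest$chrom[1],
                         start = IRanges::start(ir) - 1L,
                         end = IRanges::end(ir)), name = nm[j])
    })
  })
  names(out) <- nm
  out
}

#' Generate a cross-cell-line DHS signal matrix with planted loops
#'
#' Anchors (planted enhancers) are centred on a subset of planted
#' hypermethylated probes. Each anchor is paired with a promoter site
#' 20-450 kb away sharing a latent per-cell-line activity with the anchor
#' (noise calibrated to true correlation `link_r`); its TSS lies within
#' 1 kb of the promoter-site midpoint, so gene assignment at the default
#' 2.5 kb promoter window recovers the planted gene. Decoy DHS sites get
#' independent signal. A small number of promoter-marked DHS (overlapped by
#' H3K4me3 peaks) are added so that putative-enhancer calling has something
#' to exclude.
#'
#' @inheritParams gen_beta_matrix
#' @return List: `signal` (site-by-cell-line tibble), `anchors`
#'   (`feature_set` of planted enhancers), `dhs_set` (all sites as a
#'   `feature_set`), `h3k4me3` (`feature_set`), `target_genes` (gene-model
#'   tibble for planted targets plus background genes), and `links`
#'   (truth tibble: `probe_id`, anchor and promoter-site coordinates,
#'   `gene_id`).
#' @export
gen_dhs_signal <- function(manifest, truth, config) {
  n_links <- config$n_planted_links
  n_cells <- config$n_cell_lines
  chrom <- manifest$chrom[1]
  gl <- config$genome_length
  hw <- 75L
  withr::with_seed(config$seed + 4L, {
    hyper_pos <- manifest$pos[manifest$probe_id %in% truth$hyper_probes]
    hyper_ids <- manifest$probe_id[manifest$probe_id %in% truth$hyper_probes]
    # anchors need elbow room for their +/-500 kb windows and an interval
    # that stays on the chromosome
    ok <- hyper_pos > 600000 & hyper_pos < gl - 600000
    if (sum(ok) < n_links) {
      abort("not enough planted hyper probes away from chromosome ends")
    }
    pick <- sample(which(ok), n_links)
    anchor_pos <- hyper_pos[pick]
    anchor_ids <- hyper_ids[pick]

    off_sign <- sample(c(-1, 1), n_links, replace = TRUE)
    off <- off_sign * round(runif(n_links, 20000, 450000))
    prom_mid <- as.integer(anchor_pos + off)
    tss <- as.integer(prom_mid + round(runif(n_links, -1000, 1000)))
    gene_id <- sprintf("TGT%03d", seq_len(n_links))

    decoy_anchor <- sample.int(n_links, config$n_decoy_dhs, replace = TRUE)
    decoy_off <- sample(c(-1, 1), config$n_decoy_dhs, replace = TRUE) *
      round(runif(config$n_decoy_dhs, 5000, 490000))
    decoy_mid <- as.integer(anchor_pos[decoy_anchor] + decoy_off)

    n_prom_marked <- 20L
    pm_mid <- as.integer(sample.int(gl - 20000L, n_prom_marked) + 10000L)

    mids <- c(anchor_pos, prom_mid, decoy_mid, pm_mid)
    kind <- rep(c("anchor", "promoter", "decoy", "prom_marked"),
                c(n_links, n_links, config$n_decoy_dhs, n_prom_marked))

    sigma <- 2 * sqrt((1 - config$link_r) / config$link_r)
    latent <- matrix(rnorm(n_links * n_cells), nrow = n_links)
    sig_anchor <- 10 + 2 * latent +
      sigma * matrix(rnorm(n_links * n_cells), nrow = n_links)
    sig_prom <- 10 + 2 * latent +
      sigma * matrix(rnorm(n_links * n_cells), nrow = n_links)
    n_indep <- config$n_decoy_dhs + n_prom_marked
    sig_indep <- 10 + 2 * matrix(rnorm(n_indep * n_cells), nrow = n_indep)
    values <- pmax(rbind(sig_anchor, sig_prom, sig_indep), 0)

    bg_genes <- .gen_random_genes(n_links, chrom, gl, prefix = "BG")
  })
  signal <- tibble(chrom = chrom, start = as.integer(mids - hw),
                   end = as.integer(mids + hw))
  sig_cols <- as_tibble(as.data.frame(values))
  names(sig_cols) <- sprintf("cell_%03d", seq_len(n_cells))
  signal <- dplyr::bind_cols(signal, sig_cols)
  ord <- order(signal$start)
  site_kinds <- tibble(chrom = chrom, start = as.integer(mids - hw),
                       end = as.integer(mids + hw),
                       site_kind = kind)[ord, , drop = FALSE]
  signal <- signal[ord, , drop = FALSE]

  anchors <- feature_set(tibble(chrom = chrom, start = anchor_pos - hw,
                                end = anchor_pos + hw),
                         name = "planted_enhancers")
  dhs_set <- feature_set(signal[, c("chrom", "start", "end")], name = "dhs")
  pm_rows <- site_kinds$site_kind == "prom_marked"
  h3k4me3 <- feature_set(tibble(chrom = chrom,
                                start = pmax(signal$start[pm_rows] - 200L, 0L),
                                end = signal$end[pm_rows] + 200L),
                         name = "h3k4me3")
  target_genes <- gene_models(
    gene_id, rep(chrom, n_links), rep("+", n_links), tss,
    lapply(tss, function(t) t), lapply(tss, function(t) t + 500L))
  genes_all <- bind_rows(target_genes, bg_genes)
  links <- tibble(probe_id = anchor_ids, enh_chrom = chrom,
                  enh_start = anchor_pos - hw, enh_end = anchor_pos + hw,
                  prom_start = prom_mid - hw, prom_end = prom_mid + hw,
                  gene_id = gene_id)
  list(signal = signal, site_kinds = site_kinds, anchors = anchors,
       dhs_set = dhs_set, h3k4me3 = h3k4me3, target_genes = genes_all,
       links = links)
}

#' Generate a peak set covering a fraction of the genome
#'
#' Random non-overlapping intervals emulating looping-factor (CTCF /
#' cohesin) binding peaks, used as the partition for the RRBS mutual
#' exclusivity analysis.
#'
#' @param config A [synth_config()].
#' @param coverage_fraction Approximate fraction of the chromosome covered.
#' @param mean_width Mean peak width, bp.
#' @param name Set label.
#' @return A `feature_set`.
#' @export
gen_peak_set <- function(config, coverage_fraction = 0.1,
                         mean_width = 2000L, name = "looping_factor") {
  n_peaks <- max(1L, round(coverage_fraction * config$genome_length /
                             mean_width))
  withr::with_seed(config$seed + 5L, {
    starts <- sort(sample.int(config$genome_length - 2L * mean_width,
                              n_peaks))
    widths <- pmax(50L, rpois(n_peaks, mean_width))
  })
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L,
                                         end = starts + widths))
  feature_set(tibble(chrom = "chr1", start = IRanges::start(ir) - 1L,
                     end = IRanges::end(ir)), name = name)
}

#' Generate RRBS-style per-CpG methylation records
#'
#' CpGs outside the peak set draw beta from a bimodal high/low mixture (the
#' genome-wide RRBS shape); CpGs inside peaks draw from a near-zero mode
#' with probability `exclusivity_strength` and from the outside mixture
#' otherwise, so the peak/methylation mutual exclusivity can be dialed from
#' absent (0) to complete (1). Coverage includes sub-5X records at the
#' configured fraction, to exercise the coverage filter.
#'
#' @param peaks A `feature_set` of binding peaks.
#' @param config A [synth_config()].
#' @param seed Stream seed.
#' @return Tibble `chrom`, `pos`, `coverage`, `beta`.
#' @export
gen_rrbs <- function(peaks, config, seed = config$seed + 6L) {
  n <- config$n_rrbs
  s <- config$exclusivity_strength
  withr::with_seed(seed, {
    pos <- sort(sample.int(config$genome_length - 1L, n))
    rec <- tibble(chrom = "chr1", pos = as.integer(pos))
    in_peak <- position_overlaps(rec, peaks)
    mix_high <- rbinom(n, 1, 0.5) == 1
    beta_out <- ifelse(mix_high, rbeta(n, 18, 2), rbeta(n, 2, 18))
    beta_low <- rbeta(n, 1, 15)
    suppressed <- in_peak & (runif(n) < s)
    beta <- ifelse(suppressed, beta_low, beta_out)
    low_cov <- runif(n) < config$low_coverage_frac
    coverage <- ifelse(low_cov, sample(0:4, n, replace = TRUE),
                       5L + rpois(n, 25))
  })
  mutate(rec, coverage = as.integer(coverage), beta = beta)
}

#' Generate a per-gene expression table with planted down-regulation
#'
#' Planted down-regulated genes (the targets of planted enhancer-promoter
#' links) get fold changes well below 1 with small adjusted p-values;
#' every other gene gets a fold change near 1 and a uniform adjusted p, so
#' about 5% of non-planted genes cross a 0.05 threshold by design.
#'
#' @param genes Gene-model tibble; the table covers every gene in it.
#' @param down_genes Character vector of planted down-regulated gene ids.
#' @param config A [synth_config()].
#' @return Tibble `gene_id`, `fold_change`, `p_adj`.
#' @export
gen_expression <- function(genes, down_genes, config) {
  n <- nrow(genes)
  is_down <- genes$gene_id %in% down_genes
  withr::with_seed(config$seed + 7L, {
    fc <- exp(rnorm(n, 0, 0.05))
    p <- runif(n)
    fc[is_down] <- runif(sum(is_down), 0.3, 0.7)
    p[is_down] <- 10^runif(sum(is_down), -8, -3)
  })
  tibble(gene_id = genes$gene_id, fold_change = fc, p_adj = p)
}

#' Generate the complete synthetic study with ground truth
#'
#' Produces every input the pipeline consumes: manifest with CGI / gene
#' annotation, beta matrices for the primary cohort and (optionally) a
#' second cohort with partially concordant planted effects, feature sets
#' with planted enrichment, a DHS signal matrix with planted
#' enhancer-promoter pairs, H3K4me3 peaks for putative-enhancer calling,
#' RRBS records with planted peak/methylation exclusivity, and an
#' expression table with the planted link targets down-regulated.
#'
#' @param config A [synth_config()].
#' @param second_cohort Generate a concordant second cohort (for the
#'   cross-cohort overlap stage).
#' @param concordance Fraction of the primary cohort's planted probes that
#'   are also planted (same direction) in the second cohort.
#' @return A list of class `synth_bundle`; the `truth` element records all
#'   planted entities.
#' @export
gen_synthetic_study <- function(config = synth_config(),
                                second_cohort = TRUE, concordance = 0.6) {
  mf <- gen_manifest(config)
  truth <- plant_truth(mf$manifest, config)
  bm <- gen_beta_matrix(mf$manifest, truth, config)
  fs <- gen_feature_sets(mf$manifest, truth, config)
  dhs <- gen_dhs_signal(mf$manifest, truth, config)
  rrbs_peaks <- gen_peak_set(config)
  rrbs <- gen_rrbs(rrbs_peaks, config)
  genes_all <- bind_rows(mf$genes, dhs$target_genes)
  expr <- gen_expression(genes_all, dhs$links$gene_id, config)
  truth$enriched_features <- sprintf("enriched_%d",
                                     seq_len(config$n_enriched_features))
  truth$links <- dhs$links
  truth$down_genes <- dhs$links$gene_id
  bundle <- list(config = config, manifest = mf$manifest, cgi = mf$cgi,
                 genes = genes_all, betas = bm$betas, samples = bm$samples,
                 n_clipped = bm$n_clipped, feature_sets = fs,
                 signal = dhs$signal, site_kinds = dhs$site_kinds,
                 dhs_set = dhs$dhs_set,
                 h3k4me3 = dhs$h3k4me3, anchors = dhs$anchors,
                 rrbs_peaks = rrbs_peaks, rrbs = rrbs, expression = expr,
                 truth = truth)
  if (second_cohort) {
    truth_b <- .concordant_truth(mf$manifest, truth, config, concordance)
    bm_b <- gen_beta_matrix(mf$manifest, truth_b, config,
                            seed = config$seed + 8L)
    bundle$betas_b <- bm_b$betas
    bundle$samples_b <- bm_b$samples
    bundle$truth_b <- truth_b
  }
  structure(bundle, class = "synth_bundle")
}

# Second-cohort truth: `concordance` of cohort-A planted probes kept in the
# same direction, set sizes preserved by refilling from unplanted probes.
.concordant_truth <- function(manifest, truth, config, concordance) {
  withr::with_seed(config$seed + 9L, {
    unplanted <- setdiff(manifest$probe_id,
                         c(truth$hyper_probes, truth$hypo_probes))
    refill <- sample(unplanted)
    take <- function(set) {
      n_keep <- round(concordance * length(set))
      keep <- sample(set, n_keep)
      new <- refill[seq_len(length(set) - n_keep)]
      refill <<- refill[-seq_len(length(set) - n_keep)]
      c(keep, new)
    }
    hyper_b <- take(truth$hyper_probes)
    hypo_b <- take(truth$hypo_probes)
  })
  structure(list(hyper_probes = hyper_b, hypo_probes = hypo_b),
            class = "truth_set")
}

#' Write a synthetic bundle to disk as plain-text files
#'
#' Emits `manifest.tsv` (1-based positions, the array-manifest convention
#' that [read_manifest()] expects by default), `betas.tsv`, `samples.tsv`,
#' `cgi.bed`, `genes.tsv`, `features/*.bed`, `dhs_signal.tsv`, `h3k4me3.bed`,
#' `rrbs_peaks.bed`, `rrbs.tsv`, `expression.tsv` and `truth.json`; plus
#' `betas_b.tsv` / `samples_b.tsv` when a second cohort is present. Given
#' the same configuration the emitted files are byte-identical.
#'
#' @param bundle A [gen_synthetic_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "features"), showWarnings = FALSE)
  m <- bundle$manifest[, c("probe_id", "chrom", "pos")]
  m$pos <- m$pos + 1L
  readr::write_tsv(m, file.path(dir, "manifest.tsv"))
  readr::write_tsv(bundle$betas, file.path(dir, "betas.tsv"))
  readr::write_tsv(bundle$samples, file.path(dir, "samples.tsv"))
  write_feature_bed(bundle$cgi, file.path(dir, "cgi.bed"))
  write_gene_models(bundle$genes, file.path(dir, "genes.tsv"))
  for (fs in bundle$feature_sets) {
    write_feature_bed(fs, file.path(dir, "features",
                                    paste0(set_name(fs), ".bed")))
  }
  write_signal_matrix(bundle$signal, file.path(dir, "dhs_signal.tsv"))
  write_feature_bed(bundle$h3k4me3, file.path(dir, "h3k4me3.bed"))
  write_feature_bed(bundle$rrbs_peaks, file.path(dir, "rrbs_peaks.bed"))
  readr::write_tsv(bundle$rrbs, file.path(dir, "rrbs.tsv"))
  readr::write_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  truth <- bundle$truth
  truth$links <- as.data.frame(truth$links)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$betas_b)) {
    readr::write_tsv(bundle$betas_b, file.path(dir, "betas_b.tsv"))
    readr::write_tsv(bundle$samples_b, file.path(dir, "samples_b.tsv"))
  }
  invisible(dir)
}
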