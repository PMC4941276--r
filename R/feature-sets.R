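#' Construct a feature set of genomic intervals
#'
#' A feature set is a tibble of half-open, 0-based genomic intervals
#' (`chrom`, `start`, `end`), sorted by chromosome and start, carrying a
#' `set_name` attribute. It is the container for ChIP-seq peaks, DNase
#' hypersensitive sites (DHS), CpG islands, enhancers and any other interval
#' collection the pipeline consumes.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (extra columns
#'   are kept).
#' @param name Label for the set, e.g. `"H3K27ac_AG09319"`.
#' @return A sorted tibble of class `feature_set`.
#' @examples
#' feature_set(data.frame(chrom = "chr1", start = c(100, 50), end = c(200, 80)))
#' @export
feature_set <- function(x, name = "features") {
  x <- as_tibble(x)
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("feature set is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (nrow(x) > 0) {
    bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$start >= x$end |
                   x$start < 0)
    if (length(bad) > 0) {
      abort(paste0("invalid interval(s) at row(s) ",
                   paste(head(bad, 5), collapse = ", "),
                   ": need 0 <= start < end"))
    }
  }
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  attr(x, "set_name") <- name
  class(x) <- unique(c("feature_set", class(x)))
  x
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", set_name(x), ": ", nrow(x), " interval(s) on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  NextMethod()
}

#' Name of a feature set
#' @param x A `feature_set`.
#' @return The set label (character scalar).
#' @export
set_name <- function(x) {
  nm <- attr(x, "set_name")
  if (is.null(nm)) "features" else nm
}

#' Read a BED3+ file into a feature set
#'
#' Interprets coordinates as 0-based half-open (the BED convention). Lines
#' starting with `track`, `browser` or `#` are skipped; columns beyond the
#' third are ignored. Fields may be tab- or space-separated.
#'
#' @param path Path to a BED file.
#' @param name Label for the resulting set; defaults to the file base name.
#' @return A `feature_set` tibble.
#' @export
read_feature_bed <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(name)) name <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0) {
    return(feature_set(tibble(chrom = character(), start = integer(),
                              end = integer()), name = name))
  }
  fields <- strsplit(trimws(lines[rows]), "[ \t]+")
  parsed <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- fields[[i]]
    lineno <- rows[i]
    if (length(f) < 3) {
      abort(paste0("line ", lineno, ": expected >= 3 fields, got ", length(f)))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(paste0("line ", lineno, ": non-integer coordinates '", f[2],
                   "', '", f[3], "'"))
    }
    if (start >= end) {
      abort(paste0("line ", lineno, ": start >= end (", start, " >= ", end, ")"))
    }
    parsed[[i]] <- list(chrom = f[1], start = start, end = end)
  }
  feature_set(bind_rows(parsed), name = name)
}

#' Write a feature set as BED3
#'
#' @param features A `feature_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_bed <- function(features, path) {
  features <- feature_set(features, name = set_name(features))
  readr::write_tsv(features[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

# Split (chrom, start0, end0) into per-chromosome IRanges (1-based closed).
.ranges_by_chrom <- function(chrom, start0, end0) {
  idx <- split(seq_along(chrom), chrom)
  lapply(idx, function(i) {
    list(idx = i, ir = IRanges::IRanges(start = start0[i] + 1L, end = end0[i]))
  })
}

#' Does each position fall inside a feature?
#'
#' Overlap is evaluated at single-base resolution: a position `pos` (0-based)
#' overlaps an interval `[start, end)` iff `start <= pos < end`. This is the
#' convention for counting overlap between a CpG (the cytosine base) and a
#' called peak.
#'
#' @param positions A data frame with columns `chrom` and `pos` (0-based).
#' @param features A `feature_set`.
#' @return Logical vector, one element per row of `positions`.
#' @export
position_overlaps <- function(positions, features) {
  positions <- as_tibble(positions)
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  out <- logical(nrow(positions))
  if (nrow(positions) == 0 || nrow(features) == 0) return(out)
  feat <- .ranges_by_chrom(features$chrom, features$start, features$end)
  pos <- .ranges_by_chrom(positions$chrom, positions$pos, positions$pos + 1L)
  for (chr in intersect(names(pos), names(feat))) {
    hits <- IRanges::countOverlaps(pos[[chr]]$ir, feat[[chr]]$ir) > 0
    out[pos[[chr]]$idx] <- hits
  }
  out
}

#' Distance from each position to the nearest feature
#'
#' Returns 0 for positions inside an interval, otherwise the gap in base
#' pairs to the nearest interval on the same chromosome, counted as the
#' number of bases strictly between the position and the interval's covered
#' bases (so position 300 against `[100, 200)` is 100 bp away, and a
#' position immediately flanking an interval is at distance 0). Positions
#' on a chromosome with no feature get `NA` (the caller decides how to
#' treat feature-free chromosomes).
#'
#' @inheritParams position_overlaps
#' @return Integer vector of distances (`NA` where no feature shares the
#'   chromosome).
#' @export
distance_to_nearest <- function(positions, features) {
  positions <- as_tibble(positions)
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  out <- rep(NA_integer_, nrow(positions))
  if (nrow(positions) == 0 || nrow(features) == 0) return(out)
  feat <- .ranges_by_chrom(features$chrom, features$start, features$end)
  pos <- .ranges_by_chrom(positions$chrom, positions$pos, positions$pos + 1L)
  for (chr in intersect(names(pos), names(feat))) {
    hits <- IRanges::distanceToNearest(pos[[chr]]$ir, feat[[chr]]$ir)
    d <- rep(NA_integer_, length(pos[[chr]]$ir))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    out[pos[[chr]]$idx] <- d
  }
  out
}

#' Annotate positions by CpG-island context
#'
#' Classifies each position relative to the nearest CpG island (CGI):
#' `island` when inside a CGI, `shore` within 2 kb, `shelf` between 2 and
#' 4 kb, and `open_sea` beyond 4 kb (the standard Illumina convention;
#' open sea is defined as more than 4 kb from the closest CGI). Positions on
#' chromosomes carrying no CGI are open sea.
#'
#' @inheritParams position_overlaps
#' @param cgis A `feature_set` of CpG islands.
#' @param shore_max,shelf_max Outer bounds (bp) of the shore and shelf bands.
#' @return Factor with levels `island`, `shore`, `shelf`, `open_sea`.
#' @export
annotate_cgi_context <- function(positions, cgis, shore_max = 2000L,
                                 shelf_max = 4000L) {
  d <- distance_to_nearest(positions, cgis)
  ctx <- ifelse(is.na(d) | d > shelf_max, "open_sea",
                ifelse(d == 0L, "island",
                       ifelse(d <= shore_max, "shore", "shelf")))
  factor(ctx, levels = c("island", "shore", "shelf", "open_sea"))
}

#' Annotate positions by gene context
#'
#' Assigns each position exactly one of `promoter`, `exon`, `intron`,
#' `intergenic`, with precedence promoter > exon > intron. A position is a
#' promoter hit when it lies within `promoter_halfwidth` bp of any TSS
#' (default 2.5 kb, the window used to call a site a gene promoter); an exon
#' hit when inside any annotated exon; an intron hit when inside a gene span
#' but no exon.
#'
#' @inheritParams position_overlaps
#' @param genes Gene models as returned by [gene_models()] /
#'   [read_gene_models()].
#' @param promoter_halfwidth Half-width of the promoter window around the
#'   TSS, in bp.
#' @return Factor with levels `promoter`, `exon`, `intron`, `intergenic`.
#' @export
annotate_gene_context <- function(positions, genes,
                                  promoter_halfwidth = 2500L) {
  positions <- as_tibble(positions)
  n <- nrow(positions)
  if (nrow(genes) == 0) {
    return(factor(rep("intergenic", n),
                  levels = c("promoter", "exon", "intron", "intergenic")))
  }
  hw <- as.integer(promoter_halfwidth)
  # |pos - tss| <= hw  <=>  pos in [tss - hw, tss + hw + 1) half-open
  prom <- feature_set(tibble(
    chrom = genes$chrom,
    start = pmax(0L, genes$tss - hw),
    end = genes$tss + hw + 1L
  ), name = "promoters")
  exon_tbl <- tibble(
    chrom = rep(genes$chrom, lengths(genes$exon_starts)),
    start = unlist(genes$exon_starts),
    end = unlist(genes$exon_ends)
  )
  exons <- feature_set(exon_tbl, name = "exons")
  spans <- feature_set(tibble(
    chrom = genes$chrom,
    start = pmin(vapply(genes$exon_starts, min, integer(1)), genes$tss),
    end = pmax(vapply(genes$exon_ends, max, integer(1)), genes$tss + 1L)
  ), name = "gene_spans")
  in_prom <- position_overlaps(positions, prom)
  in_exon <- position_overlaps(positions, exons)
  in_span <- position_overlaps(positions, spans)
  ctx <- ifelse(in_prom, "promoter",
                ifelse(in_exon, "exon",
                       ifelse(in_span, "intron", "intergenic")))
  factor(ctx, levels = c("promoter", "exon", "intron", "intergenic"))
}

#' Build a gene-model table
#'
#' @param gene_id Character vector of gene identifiers.
#' @param chrom Chromosome per gene.
#' @param strand `"+"` or `"-"`; used only to place the TSS.
#' @param tss 0-based TSS coordinate.
#' @param exon_starts,exon_ends Lists of integer vectors (0-based half-open),
#'   sorted and non-overlapping within each gene.
#' @return A tibble with list-columns `exon_starts`, `exon_ends`.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, exon_starts, exon_ends) {
  stopifnot(length(gene_id) == length(chrom),
            length(exon_starts) == length(gene_id),
            length(exon_ends) == length(gene_id),
            all(strand %in% c("+", "-")))
  for (i in seq_along(gene_id)) {
    s <- as.integer(exon_starts[[i]]); e <- as.integer(exon_ends[[i]])
    if (length(s) == 0 || length(s) != length(e) || any(s >= e) ||
        is.unsorted(s, strictly = TRUE) ||
        (length(s) > 1 && any(s[-1] < e[-length(e)]))) {
      abort(paste0("gene ", gene_id[i],
                   ": exons must be sorted, non-empty and non-overlapping"))
    }
  }
  if (anyDuplicated(gene_id)) abort("duplicated gene_id")
  tibble(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = as.character(strand), tss = as.integer(tss),
         exon_starts = lapply(exon_starts, as.integer),
         exon_ends = lapply(exon_ends, as.integer))
}

#' Read a probe manifest
#'
#' Expects a TSV with header `probe_id`, `chrom`, `pos`. Array manifests are
#' usually 1-based; with `base = 1` (the default) positions are converted to
#' the package's internal 0-based convention on read.
#'
#' @param path TSV path.
#' @param base Coordinate base of the file: `1` (array-manifest style,
#'   default) or `0`.
#' @return A tibble `probe_id`, `chrom`, `pos` (0-based).
#' @export
read_manifest <- function(path, base = 1) {
  stopifnot(base %in% c(0, 1))
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         probe_id = readr::col_character(),
                         chrom = readr::col_character(),
                         pos = readr::col_integer()))
  if (anyDuplicated(m$probe_id)) abort("manifest has duplicated probe_id")
  if (any(is.na(m$pos))) abort("manifest has missing positions")
  m$pos <- m$pos - as.integer(base)
  if (any(m$pos < 0)) abort("negative position after base conversion")
  m
}

#' Read gene models from TSV
#'
#' Columns: `gene_id`, `chrom`, `strand`, `tss`, `exon_starts`, `exon_ends`,
#' the last two as comma-separated integer lists (0-based half-open).
#'
#' @param path TSV path.
#' @return A gene-model tibble (see [gene_models()]).
#' @export
read_gene_models <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  parse_list <- function(x) lapply(strsplit(x, ","), function(v) as.integer(v))
  gene_models(g$gene_id, g$chrom, g$strand, as.integer(g$tss),
              parse_list(g$exon_starts), parse_list(g$exon_ends))
}

#' Write gene models to TSV
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  flat <- tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = genes$tss,
    exon_starts = vapply(genes$exon_starts, paste, character(1), collapse = ","),
    exon_ends = vapply(genes$exon_ends, paste, character(1), collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}
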