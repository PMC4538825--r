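## Catalog derivation: peaks shared between wild-type and antigen-null
## profiles are the antibody's false positives; their union across
## antibodies is the Phantom Peak catalog.  High read density regions
## (HDRs) derived from input chromatin flag copy-number/accessibility
## artifacts, a distinct class from immunoprecipitation-stage artifacts.

#' Peaks shared between wild-type and antigen-null profiles
#'
#' Returns the wild-type peaks that overlap some mutant peak by at least
#' `min_overlap` bp.  Signal that survives removal of the antigen cannot
#' reflect specific immunoprecipitation, so these are the profile's false
#' positives.  The WT intervals (not intersection bases) are reported,
#' matching peak-count bookkeeping per profile.
#'
#' @param wt,mutant peak `GRanges` for the two genotypes.
#' @param min_overlap minimum shared bases (bp); default 50.
#' @return the common peaks as a `GRanges` subset of `wt`, with counts in
#'   attribute `counts` (`wt_only`, `mutant_only`, `common`).
#' @export
common_peaks <- function(wt, mutant, min_overlap = 50L) {
  .check_granges(wt); .check_granges(mutant)
  hits_wt <- overlap_hits(wt, mutant, min_overlap)$hit
  hits_mut <- overlap_hits(mutant, wt, min_overlap)$hit
  out <- wt[hits_wt]
  attr(out, "counts") <- c(wt_only = sum(!hits_wt),
                           mutant_only = sum(!hits_mut),
                           common = sum(hits_wt))
  out
}

#' Build a Phantom Peak catalog from common-peak sets
#'
#' Merges the union of all supplied common-peak sets (base-wise, with
#' `merge_gap`); every resulting locus records which input sets
#' contributed to it.  Order-independent.
#'
#' @param common_sets named list of `GRanges` (names are provenance
#'   labels, e.g. the antibody or factor).
#' @param merge_gap gap (bp) at or below which loci merge; default 0.
#' @return an object of class `phantom_catalog`: list with `loci`
#'   (merged `GRanges` with a comma-separated `provenance` column) and
#'   `parameters`.
#' @export
build_catalog <- function(common_sets, merge_gap = 0L) {
  if (!is.list(common_sets) || length(common_sets) < 1)
    stop("'common_sets' must be a non-empty list of GRanges")
  if (is.null(names(common_sets)) || any(!nzchar(names(common_sets))))
    names(common_sets) <- sprintf("set%d", seq_along(common_sets))
  lapply(common_sets, .check_granges, arg = "common_sets[[i]]")
  stripped <- lapply(common_sets, function(g) {
    S4Vectors::mcols(g) <- NULL
    g
  })
  pooled <- suppressWarnings(do.call(c, unname(stripped)))
  loci <- merge_intervals(pooled, min_gap = merge_gap)
  prov <- character(length(loci))
  for (lbl in names(stripped)) {
    hit <- overlap_hits(loci, stripped[[lbl]], min_overlap = 1L)$hit
    prov[hit] <- ifelse(nzchar(prov[hit]), paste0(prov[hit], ",", lbl), lbl)
  }
  S4Vectors::mcols(loci)$provenance <- prov
  structure(list(loci = loci,
                 parameters = list(merge_gap = merge_gap,
                                   labels = names(common_sets))),
            class = "phantom_catalog")
}

#' @export
print.phantom_catalog <- function(x, ...) {
  cat(sprintf("phantom_catalog: %d loci (%s bp) from sets: %s\n",
              length(x$loci), format(coverage_bp(x$loci), big.mark = ","),
              paste(x$parameters$labels, collapse = ", ")))
  invisible(x)
}

#' Coerce a peak set to a phantom_catalog
#'
#' Lets externally supplied catalogs (e.g. read from BED) flow into the
#' screening and annotation stages.
#'
#' @param loci a `GRanges` (merged on coercion).
#' @param label provenance label.
#' @return a `phantom_catalog`.
#' @export
as_phantom_catalog <- function(loci, label = "external") {
  build_catalog(stats::setNames(list(loci), label))
}

# top-k order-statistic threshold: k = max(1, floor(fraction * n)),
# ties at the threshold all included
.top_threshold <- function(values, fraction) {
  if (fraction <= 0 || fraction >= 1)
    stop("'top_fraction' must be in (0, 1)")
  n <- length(values)
  if (!n) stop("no values to threshold")
  if (length(unique(values)) == 1L)
    stop("quantile degenerate: all values are equal")
  k <- max(1L, floor(fraction * n))
  sort(values, decreasing = TRUE)[k]
}

#' Derive high read density regions (HDRs) from input coverage
#'
#' Bins whose value reaches the genome-wide top-`top_fraction` threshold
#' (all bins, zeros included; ties at the threshold kept) are selected
#' and merged into regions.  In the reference analysis the top 1% of
#' input signal yields regions covering roughly 3% of the genome.
#'
#' @param input a `coverage_track` of input chromatin.
#' @param top_fraction fraction of top-scoring bins; default 0.01.
#' @param merge_gap merge gap (bp); default 0.
#' @return an object of class `hdr_set`: list with `regions` (merged
#'   `GRanges`), `top_fraction`, `source_track`, `genome_fraction`
#'   (covered bases / genome bases).
#' @export
derive_hdrs <- function(input, top_fraction = 0.01, merge_gap = 0L) {
  stopifnot(inherits(input, "coverage_track"))
  all_values <- unlist(input$values, use.names = FALSE)
  if (!length(all_values)) stop("input track is empty")
  thr <- .top_threshold(all_values, top_fraction)
  bs <- input$bin_size
  regions <- list()
  for (chr in names(input$values)) {
    v <- input$values[[chr]]
    idx <- which(v >= thr)
    if (length(idx))
      regions[[chr]] <- GenomicRanges::GRanges(
        chr, IRanges::IRanges((idx - 1L) * bs + 1L, width = bs))
  }
  gr <- if (length(regions)) {
    merge_intervals(suppressWarnings(do.call(c, unname(regions))), merge_gap)
  } else GenomicRanges::GRanges()
  genome_bp <- sum(vapply(input$values, length, 0L)) * bs
  structure(list(regions = gr, top_fraction = top_fraction,
                 source_track = input$label,
                 genome_fraction = coverage_bp(gr) / genome_bp),
            class = "hdr_set")
}

#' @export
print.hdr_set <- function(x, ...) {
  cat(sprintf(
    "hdr_set: %d regions (top %.3g%% of '%s' bins, %.2f%% of the genome)\n",
    length(x$regions), 100 * x$top_fraction, x$source_track,
    100 * x$genome_fraction))
  invisible(x)
}

#' Fraction of catalog loci overlapping HDRs
#'
#' Optionally also returns the catalog with HDR-overlapping loci removed.
#' By default the catalog retains such loci (the overlap is reported, not
#' filtered), with `filter = TRUE` to drop them.
#'
#' @param catalog a `phantom_catalog`.
#' @param hdrs an `hdr_set`.
#' @param min_overlap minimum overlap (bp); default 1 (most conservative
#'   flagging).
#' @param filter if `TRUE`, also return the filtered catalog.
#' @return list with `fraction`, `hit` (logical per locus) and, when
#'   `filter = TRUE`, `filtered` (a `phantom_catalog`).
#' @export
hdr_overlap_fraction <- function(catalog, hdrs, min_overlap = 1L,
                                 filter = FALSE) {
  stopifnot(inherits(catalog, "phantom_catalog"), inherits(hdrs, "hdr_set"))
  if (!length(catalog$loci))
    return(list(fraction = NA_real_, hit = logical(0)))
  hit <- overlap_hits(catalog$loci, hdrs$regions, min_overlap)$hit
  out <- list(fraction = mean(hit), hit = hit)
  if (filter) {
    filt <- catalog
    filt$loci <- catalog$loci[!hit]
    filt$parameters$hdr_filtered <- TRUE
    out$filtered <- filt
  }
  out
}
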