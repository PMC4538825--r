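## Interval kernel: exact algebra on genomic intervals.  Every downstream
## stage (catalog derivation, HDR filtering, annotation, overlap testing)
## is built on these operations.  Intervals are GRanges (1-based, closed);
## strand is carried but ignored by the algebra -- the overlap criteria of
## the analysis are strand-blind.

#' Construct a GRanges from chromosome/start/end vectors
#'
#' Convenience constructor used throughout the package.  Coordinates are
#' 1-based closed (the GRanges convention).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 1-based closed; `end >= start`.
#' @param strand strand codes (`"+"`, `"-"` or `"*"`); recycled.
#' @param ... further metadata columns (e.g. `score`, `name`).
#' @return a sorted `GRanges`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", ...) {
  if (any(start < 1)) stop("interval start must be >= 1 (1-based closed)")
  if (any(end < start)) stop("interval end must be >= start")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  mc <- list(...)
  if (length(mc)) S4Vectors::mcols(gr)[names(mc)] <- mc
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

.check_granges <- function(x, arg = deparse(substitute(x))) {
  if (!methods::is(x, "GRanges"))
    stop(sprintf("'%s' must be a GRanges", arg))
  invisible(x)
}

#' Merge overlapping or nearby intervals
#'
#' Intervals separated by at most `min_gap` bases are joined; at
#' `min_gap = 0` overlapping and abutting intervals merge.  Idempotent,
#' and base-identical to its input for already-merged sets.
#'
#' @param s a `GRanges`.
#' @param min_gap non-negative gap (bp) below or at which intervals join.
#' @return a merged, sorted `GRanges` (no metadata columns).
#' @export
merge_intervals <- function(s, min_gap = 0L) {
  .check_granges(s)
  if (length(min_gap) != 1L || is.na(min_gap) || min_gap < 0)
    stop("'min_gap' must be a single non-negative number")
  GenomicRanges::reduce(s, min.gapwidth = min_gap + 1L, ignore.strand = TRUE)
}

#' Base-wise intersection of two interval sets
#'
#' @param a,b `GRanges` objects.
#' @return merged `GRanges` covering exactly the bases present in both.
#' @export
intersect_sets <- function(a, b) {
  .check_granges(a); .check_granges(b)
  suppressWarnings(GenomicRanges::intersect(
    merge_intervals(a), merge_intervals(b), ignore.strand = TRUE
  ))
}

#' Overlap hits with a minimum-overlap criterion
#'
#' Marks each query interval that shares at least `min_overlap` bases with
#' some subject interval (evaluated per subject interval, not summed), and
#' reports all qualifying pairs.
#'
#' @param query,subject `GRanges` objects.
#' @param min_overlap minimum shared bases (bp, >= 1).
#' @return list with `hit` (logical, one per query) and `pairs`
#'   (data.frame of `query_idx`, `subject_idx`).
#' @export
overlap_hits <- function(query, subject, min_overlap = 1L) {
  .check_granges(query); .check_granges(subject)
  if (length(min_overlap) != 1L || is.na(min_overlap) || min_overlap < 1)
    stop("'min_overlap' must be a single value >= 1")
  # chromosome names are taken verbatim; sets over disjoint chromosome
  # universes are a legitimate comparison (zero hits), so the seqlevel
  # union warning is suppressed
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(query, subject,
                                minoverlap = as.integer(min_overlap),
                                ignore.strand = TRUE))
  hit <- logical(length(query))
  hit[S4Vectors::queryHits(ov)] <- TRUE
  list(hit = hit,
       pairs = data.frame(query_idx = S4Vectors::queryHits(ov),
                          subject_idx = S4Vectors::subjectHits(ov)))
}

#' Total distinct bases covered by an interval set
#'
#' Overlapping bases are counted once.
#'
#' @param s a `GRanges`.
#' @return total covered bases (numeric).
#' @export
coverage_bp <- function(s) {
  .check_granges(s)
  sum(as.numeric(GenomicRanges::width(merge_intervals(s))))
}

#' Fixed-width windows centered on genomic points
#'
#' Each point (e.g. a TSS) becomes a window of `total_width` bases centered
#' on it, optionally clipped at chromosome boundaries.  The output is not
#' merged; use [merge_intervals()] for a reference-region union.
#'
#' @param points data.frame with columns `chrom`, `pos` (1-based base
#'   coordinate of the point) and optionally `strand`.
#' @param total_width even window width (bp, >= 2).
#' @param chrom_sizes optional named vector of chromosome lengths (bp) for
#'   clipping at the right end; windows are always clipped at position 1.
#' @return `GRanges`, one window per point, in input order.
#' @export
windows_around_points <- function(points, total_width, chrom_sizes = NULL) {
  if (!is.data.frame(points) || !all(c("chrom", "pos") %in% names(points)))
    stop("'points' must be a data.frame with columns 'chrom' and 'pos'")
  if (length(total_width) != 1L || total_width < 2 || total_width %% 2 != 0)
    stop("'total_width' must be a single positive even number")
  hw <- total_width / 2
  start <- pmax(1, points$pos - hw)
  end <- points$pos + hw - 1
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[as.character(points$chrom)]
    if (anyNA(lim))
      stop("chromosomes missing from 'chrom_sizes': ",
           paste(unique(points$chrom[is.na(lim)]), collapse = ", "))
    end <- pmin(end, lim)
  }
  strand <- if ("strand" %in% names(points)) points$strand else "*"
  GenomicRanges::GRanges(points$chrom, IRanges::IRanges(start, end),
                         strand = strand)
}

#' Interval midpoints (lower-median base)
#'
#' For an even-width interval the lower of the two central candidates under
#' the floor((start0 + end0)/2) rule is used, giving a deterministic
#' tie-break.
#'
#' @param s a `GRanges`.
#' @return integer vector of 1-based midpoint coordinates.
#' @export
interval_midpoints <- function(s) {
  .check_granges(s)
  # floor((start0 + end0) / 2) expressed in 1-based coordinates
  as.integer(floor((GenomicRanges::start(s) - 1 + GenomicRanges::end(s)) / 2) + 1L)
}

#' Signed distance from interval midpoints to the nearest point
#'
#' Distance is `midpoint - point` (negative when the midpoint lies left of
#' its nearest point).  Queries on chromosomes without any point get `NA`.
#'
#' @param query a `GRanges`.
#' @param points data.frame with columns `chrom` and `pos` (1-based).
#' @return numeric vector of signed distances (bp), one per query.
#' @export
distance_to_nearest_point <- function(query, points) {
  .check_granges(query)
  if (!is.data.frame(points) || nrow(points) == 0)
    stop("'points' must be a non-empty data.frame with 'chrom' and 'pos'")
  mids <- interval_midpoints(query)
  chroms <- as.character(GenomicRanges::seqnames(query))
  out <- rep(NA_real_, length(query))
  by_chr <- split(points$pos, as.character(points$chrom))
  for (chr in names(by_chr)) {
    idx <- which(chroms == chr)
    if (!length(idx)) next
    pos <- sort(by_chr[[chr]])
    # nearest via findInterval on sorted points
    lo <- findInterval(mids[idx], pos)
    cand_lo <- pos[pmax(lo, 1L)]
    cand_hi <- pos[pmin(lo + 1L, length(pos))]
    d_lo <- mids[idx] - cand_lo
    d_hi <- mids[idx] - cand_hi
    pick_lo <- lo >= 1L & (lo >= length(pos) | abs(d_lo) <= abs(d_hi))
    out[idx] <- ifelse(pick_lo, d_lo, d_hi)
  }
  out
}
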