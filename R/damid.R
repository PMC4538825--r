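## DamID: antibody-free chromatin profiling.  Binding-site intervals are
## derived from the highest-scoring methylation probes -- the top 1%
## scoring probes are extended to 1 kb and merged -- and then screened
## against the Phantom Peak catalog with the same reference-constrained
## framework as antibody profiles, giving an orthogonal check on whether
## an antibody profile's catalog overlap reflects real binding.

#' Derive binding intervals from DamID probe scores
#'
#' Probes reaching the top-`top_fraction` score threshold (ties at the
#' threshold included) become intervals of total width `extend_to`
#' centered on the probe position (clipped at the chromosome start);
#' overlapping or abutting intervals are merged.
#'
#' @param probes data.frame with columns `chrom`, `pos` (1-based), `score`
#'   (see [read_damid()]).
#' @param top_fraction fraction of top-scoring probes; default 0.01.
#' @param extend_to total extended width (bp); default 1000.
#' @return merged `GRanges` of binding intervals.
#' @export
damid_peaks <- function(probes, top_fraction = 0.01, extend_to = 1000L) {
  if (!is.data.frame(probes) || !all(c("chrom", "pos", "score") %in% names(probes)))
    stop("'probes' must be a data.frame with chrom, pos, score")
  if (nrow(probes) < 100)
    stop("need at least 100 probes (top fraction degenerate below that)")
  if (extend_to < 1) stop("'extend_to' must be >= 1")
  thr <- .top_threshold(probes$score, top_fraction)
  top <- probes[probes$score >= thr, , drop = FALSE]
  start <- pmax(1, top$pos - floor(extend_to / 2))
  gr <- GenomicRanges::GRanges(top$chrom,
                               IRanges::IRanges(start, width = extend_to))
  merge_intervals(gr)
}

#' Screen DamID-derived intervals against a catalog
#'
#' Delegates to [reference_constrained_test()] with the DamID intervals
#' as the query profile.
#'
#' @param damid_regions `GRanges` from [damid_peaks()].
#' @param catalog a `phantom_catalog` or `GRanges`.
#' @param ref a `reference_regions` object.
#' @param min_overlap minimum overlap (bp); default 50.
#' @param n_perm permutations; default 1000.
#' @param seed integer seed.
#' @param label report label; default "damid".
#' @return an `overlap_report` row (see [reference_constrained_test()]).
#' @export
damid_vs_catalog <- function(damid_regions, catalog, ref, min_overlap = 50L,
                             n_perm = 1000L, seed = 1L, label = "damid") {
  reference_constrained_test(damid_regions, catalog, ref,
                             min_overlap = min_overlap, n_perm = n_perm,
                             seed = seed, label = label)
}
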