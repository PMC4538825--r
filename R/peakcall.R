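## Fixed-width peak calling over binned coverage, plus consensus calling
## across antibody replicates.  The caller is a fully specified stand-in
## for an external fixed-width caller: sliding windows of a fixed width are
## scored against a local input background under a Poisson model, then
## reduced greedily to a non-overlapping peak set.  All downstream stages
## also accept externally produced BED peak sets, so the caller is
## bypassable.

#' Configuration for the fixed-width peak caller
#'
#' @param peak_width fixed peak width (bp, multiple of the track bin size);
#'   default 200, matching a typical sonicated chromatin fragment size.
#' @param step window stride (bp); default one bin.
#' @param min_fold_over_input minimum observed/expected fold; default 4.
#' @param poisson_alpha Poisson upper-tail significance cutoff; default 1e-4.
#' @param local_background_halfwidth half-width (bp) of the window used for
#'   the local input background; default 5000.
#' @param target_total library size both tracks are scaled to; default 1e6.
#' @return a `peak_call_config` list.
#' @export
peak_call_config <- function(peak_width = 200L, step = NULL,
                             min_fold_over_input = 4,
                             poisson_alpha = 1e-4,
                             local_background_halfwidth = 5000L,
                             target_total = 1e6) {
  if (poisson_alpha <= 0 || poisson_alpha >= 1)
    stop("'poisson_alpha' must be in (0, 1)")
  if (min_fold_over_input <= 1)
    stop("'min_fold_over_input' must be > 1")
  if (peak_width < 1) stop("'peak_width' must be >= 1")
  structure(list(peak_width = as.integer(peak_width), step = step,
                 min_fold_over_input = min_fold_over_input,
                 poisson_alpha = poisson_alpha,
                 local_background_halfwidth = as.integer(local_background_halfwidth),
                 target_total = target_total),
            class = "peak_call_config")
}

# rolling sum of k consecutive entries, length(v) - k + 1 results
.roll_sum <- function(v, k) {
  cs <- c(0, cumsum(v))
  cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]
}

#' Call fixed-width peaks against an input background
#'
#' Both tracks are normalized to `cfg$target_total` reads.  Sliding
#' windows of `peak_width` are scored by their ChIP read count; the
#' expected count is the larger of the local input mean (over +/- the
#' background half-width) and the genome-wide input mean, scaled to the
#' window width.  Windows pass when the Poisson upper tail
#' P(X >= observed) is below `poisson_alpha` and the observed/expected
#' fold reaches `min_fold_over_input`; candidates are reduced to a
#' non-overlapping set greedily in decreasing fold order (ties broken by
#' leftmost coordinate).
#'
#' @param chip,input `coverage_track` objects sharing bin size and
#'   chromosome lengths.
#' @param cfg a [peak_call_config()].
#' @return `GRanges` of fixed-width peaks with `score`
#'   (observed/expected fold) and `name` metadata columns.
#' @export
call_fixed_width_peaks <- function(chip, input, cfg = peak_call_config()) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (chip$bin_size != input$bin_size)
    stop("chip and input tracks have different bin sizes")
  if (!identical(sort(names(chip$values)), sort(names(input$values))) ||
      !all(vapply(names(chip$values),
                  function(c) length(chip$values[[c]]) == length(input$values[[c]]),
                  TRUE)))
    stop("chip and input tracks have mismatched chromosomes/lengths")
  bs <- chip$bin_size
  if (cfg$peak_width < bs) stop("'peak_width' must be >= the track bin size")
  if (cfg$peak_width %% bs != 0)
    stop("'peak_width' must be a multiple of the track bin size")
  if (chip$total_signal == 0)
    return(GenomicRanges::GRanges())
  chip <- normalize_track(chip, cfg$target_total)
  input <- normalize_track(input, cfg$target_total)
  w_bins <- cfg$peak_width %/% bs
  step_bins <- if (is.null(cfg$step)) 1L else {
    if (cfg$step %% bs != 0) stop("'step' must be a multiple of the bin size")
    max(1L, cfg$step %/% bs)
  }
  hb_bins <- max(1L, cfg$local_background_halfwidth %/% bs)
  g_mean <- input$total_signal / sum(vapply(input$values, length, 0L))
  cand <- list()
  for (chr in names(chip$values)) {
    vc <- chip$values[[chr]]; vi <- input$values[[chr]]
    if (length(vc) < w_bins) next
    obs <- .roll_sum(vc, w_bins)
    starts <- seq(1L, length(obs), by = step_bins)
    obs <- obs[starts]
    # local background: mean input per bin over window +/- halfwidth
    loc_mean <- vapply(starts, function(s) {
      lo <- max(1L, s - hb_bins)
      hi <- min(length(vi), s + w_bins - 1L + hb_bins)
      mean(vi[lo:hi])
    }, 0)
    expected <- pmax(loc_mean, g_mean) * w_bins
    ok <- expected > 0 & obs > 0
    # Poisson upper tail P(X >= obs), continuous in obs via the gamma
    # identity P(Pois(lambda) >= k) = pgamma(lambda, shape = k)
    pval <- rep(1, length(obs))
    pval[ok] <- stats::pgamma(expected[ok], shape = obs[ok])
    fold <- ifelse(ok, obs / expected, 0)
    keep <- ok & pval < cfg$poisson_alpha & fold >= cfg$min_fold_over_input
    if (any(keep))
      cand[[chr]] <- data.frame(chrom = chr,
                                start = (starts[keep] - 1L) * bs + 1L,
                                fold = fold[keep])
  }
  if (!length(cand)) return(GenomicRanges::GRanges())
  cand <- do.call(rbind, cand)
  # greedy non-overlap selection: decreasing fold, ties by leftmost
  cand <- cand[order(-cand$fold, cand$chrom, cand$start), ]
  sel <- logical(nrow(cand))
  chosen <- split(numeric(0), character(0))
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]
    prev <- chosen[[ch]]
    if (is.null(prev) || !any(abs(prev - cand$start[i]) < cfg$peak_width)) {
      sel[i] <- TRUE
      chosen[[ch]] <- c(prev, cand$start[i])
    }
  }
  cand <- cand[sel, ]
  gr <- GenomicRanges::GRanges(
    cand$chrom,
    IRanges::IRanges(cand$start, width = cfg$peak_width),
    score = cand$fold
  )
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::mcols(gr)$name <- sprintf("peak%d", seq_along(gr))
  gr
}

# single-linkage connected components over an edge list (union-find)
.components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, 0L)
}

#' Consensus peaks across replicate profiles
#'
#' Replicate peaks are chained by single linkage through the
#' `>= min_overlap` bp overlap relation; every maximal group supported by
#' at least `min_support` distinct replicates yields one consensus peak:
#' a fixed-width window centered on the score-weighted mean of member
#' centers, scored by the mean member score.  The default requires
#' support from all replicates (a conservative common peak list).
#'
#' @param replicates list of >= 2 peak `GRanges` (with `score` columns;
#'   missing scores count as weight 1).
#' @param min_support minimum number of distinct supporting replicates;
#'   default `length(replicates)`.
#' @param min_overlap minimum pairwise overlap (bp) for chaining; default 50.
#' @return consensus peak `GRanges` with `score`, `name` and `n_support`
#'   metadata columns.
#' @export
consensus_peaks <- function(replicates, min_support = length(replicates),
                            min_overlap = 50L) {
  if (!is.list(replicates) || length(replicates) < 2)
    stop("'replicates' must be a list of at least 2 peak sets")
  lapply(replicates, .check_granges, arg = "replicates[[i]]")
  if (min_support > length(replicates))
    stop("'min_support' cannot exceed the number of replicates")
  if (min_support < 1) stop("'min_support' must be >= 1")
  rep_id <- rep(seq_along(replicates), vapply(replicates, length, 0L))
  pooled <- suppressWarnings(do.call(c, unname(lapply(replicates, function(g) {
    S4Vectors::mcols(g) <- NULL
    g
  }))))
  if (!length(pooled)) return(GenomicRanges::GRanges())
  scores <- unlist(lapply(replicates, function(g) {
    s <- S4Vectors::mcols(g)$score
    if (is.null(s)) rep(1, length(g)) else s
  }))
  ov <- GenomicRanges::findOverlaps(pooled, pooled,
                                    minoverlap = as.integer(min_overlap),
                                    ignore.strand = TRUE)
  comp <- .components(length(pooled),
                      S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  mids <- interval_midpoints(pooled)
  widths <- GenomicRanges::width(pooled)
  chroms <- as.character(GenomicRanges::seqnames(pooled))
  out <- lapply(split(seq_along(pooled), comp), function(i) {
    if (length(unique(rep_id[i])) < min_support) return(NULL)
    w <- scores[i]
    if (all(w == 0)) w <- rep(1, length(i))
    center <- round(stats::weighted.mean(mids[i], w))
    width <- round(mean(widths[i]))
    # place so that interval_midpoints() of the result equals `center`
    start <- max(1, center - floor(width / 2))
    data.frame(chrom = chroms[i][1], start = start, end = start + width - 1,
               score = mean(scores[i]), n_support = length(unique(rep_id[i])))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$start, out$end),
                               score = out$score, n_support = out$n_support)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::mcols(gr)$name <- sprintf("consensus%d", seq_along(gr))
  gr
}
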