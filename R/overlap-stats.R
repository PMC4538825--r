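## Reference-constrained overlap significance.  Screening a peak set
## against the catalog asks: do more query peaks coincide with catalog
## loci than expected for peaks with the same genomic preference?  Both
## phantom loci and most chromatin-factor peaks concentrate near active
## promoters, so a genome-wide null would call almost any promoter-bound
## profile significant.  The null here conditions on that shared
## preference: each query peak is independently relocated, width
## preserved, to a uniformly random position that fits entirely inside
## the reference-region union (by default 4-kb windows centered on every
## TSS).  The asymmetric test statistic is the number of query peaks
## overlapping the catalog by at least `min_overlap` bp.

#' Build reference regions from TSS windows
#'
#' @param models a `gene_models` object (or a data.frame of points with
#'   `chrom` and `pos`).
#' @param window_total total window width centered at each TSS (bp);
#'   default 4000.
#' @param chrom_sizes optional named chromosome lengths for clipping.
#' @return an object of class `reference_regions`: list with `regions`
#'   (merged `GRanges`) and `total_bp`.
#' @export
reference_regions <- function(models, window_total = 4000L,
                              chrom_sizes = NULL) {
  pts <- if (inherits(models, "gene_models")) tss_points(models) else models
  win <- windows_around_points(pts, window_total, chrom_sizes)
  reg <- merge_intervals(win)
  if (!length(reg)) stop("reference region set is empty")
  structure(list(regions = reg, total_bp = coverage_bp(reg),
                 window_total = window_total),
            class = "reference_regions")
}

#' Coerce an interval set to reference regions
#' @param regions a `GRanges`; merged on coercion.
#' @return a `reference_regions` object.
#' @export
as_reference_regions <- function(regions) {
  reg <- merge_intervals(regions)
  if (!length(reg)) stop("reference region set is empty")
  structure(list(regions = reg, total_bp = coverage_bp(reg),
                 window_total = NA), class = "reference_regions")
}

#' Fraction of query peaks overlapping a catalog
#'
#' @param query a non-empty peak `GRanges`.
#' @param catalog a `phantom_catalog` (or `GRanges`).
#' @param min_overlap minimum overlap (bp); default 50.
#' @return list with `fraction`, `hit` (logical per query) and `n_hit`.
#' @export
overlap_fraction <- function(query, catalog, min_overlap = 50L) {
  .check_granges(query)
  loci <- if (inherits(catalog, "phantom_catalog")) catalog$loci else catalog
  if (!length(query)) stop("no peaks to screen")
  hit <- overlap_hits(query, loci, min_overlap)$hit
  list(fraction = mean(hit), hit = hit, n_hit = sum(hit))
}

## ---- null-placement machinery ----------------------------------------
## For one peak width w over a merged reference set, allowed start
## positions are those where the full peak fits inside a single region;
## they are indexed 1..A_w across regions.  Start positions giving a
## >= min_overlap bp overlap with some (merged, hence disjoint) catalog
## locus form an exact union of index intervals, so per-width success
## probability, membership tests and sampling are all exact and O(log).

.placement_space <- function(ref_regions, width, loci, min_overlap) {
  rs <- GenomicRanges::start(ref_regions)
  re <- GenomicRanges::end(ref_regions)
  rchr <- as.character(GenomicRanges::seqnames(ref_regions))
  a <- pmax(0, re - rs + 1 - width + 1)          # allowed starts per region
  offset <- cumsum(c(0, a[-length(a)]))          # index offset per region
  total <- sum(a)
  qlo <- numeric(0); qhi <- numeric(0)           # qualifying index intervals
  if (length(loci) && total > 0) {
    lchr <- as.character(GenomicRanges::seqnames(loci))
    for (j in which(a > 0)) {
      li <- which(lchr == rchr[j])
      if (!length(li)) next
      # starts s with overlap(s, s+w-1 ; locus) >= m:
      #   s in [start(locus) + m - w, end(locus) - m + 1]
      lo <- pmax(GenomicRanges::start(loci)[li] + min_overlap - width, rs[j])
      hi <- pmin(GenomicRanges::end(loci)[li] - min_overlap + 1,
                 re[j] - width + 1)
      ok <- lo <= hi
      if (any(ok)) {
        qlo <- c(qlo, offset[j] + (lo[ok] - rs[j]) + 1)
        qhi <- c(qhi, offset[j] + (hi[ok] - rs[j]) + 1)
      }
    }
  }
  if (length(qlo)) {
    # catalog loci are disjoint, but qualifying windows can touch across
    # loci; reduce to disjoint index intervals
    ir <- IRanges::reduce(IRanges::IRanges(qlo, qhi))
    qlo <- IRanges::start(ir); qhi <- IRanges::end(ir)
  }
  list(total = total, q_total = sum(qhi - qlo + 1),
       qlo = qlo, qhi = qhi, offset = offset, a = a,
       rs = rs, rchr = rchr)
}

# membership of sampled global indices in the qualifying set
.in_qualifying <- function(idx, space) {
  if (!length(space$qlo)) return(rep(FALSE, length(idx)))
  b <- as.vector(rbind(space$qlo, space$qhi + 1))
  findInterval(idx, b) %% 2L == 1L
}

# exact Poisson-binomial upper tail P(T >= t) for success probs p
.poisbinom_tail <- function(p, t) {
  if (t <= 0) return(1)
  if (t > length(p)) return(0)
  f <- 1  # distribution of the running sum, f[k+1] = P(S = k)
  for (pi in p) f <- c(f * (1 - pi), 0) + c(0, f * pi)
  sum(f[(t + 1):length(f)])
}

#' Reference-constrained overlap significance test
#'
#' Observed statistic: the number of query peaks overlapping the catalog
#' by at least `min_overlap` bp.  Null: every query peak independently
#' relocated to a uniformly random width-preserving position inside the
#' reference-region union (peaks observed outside the reference are
#' still relocated into it -- the test conditions on the shared genomic
#' preference).  `p_perm` uses `n_perm` Monte-Carlo relocations with the
#' add-one estimator; `p_analytic` is the exact Poisson-binomial tail
#' over per-peak success probabilities computed by enumeration of allowed
#' start positions (a plain binomial tail when all peaks share one
#' width).
#'
#' Peaks wider than every reference region cannot be placed; they are
#' excluded from the test and listed in the report.
#'
#' @param query a non-empty peak `GRanges`.
#' @param catalog a `phantom_catalog` or `GRanges`.
#' @param ref a `reference_regions` object.
#' @param min_overlap minimum overlap (bp); default 50.
#' @param n_perm number of permutations (>= 100); default 1000.
#' @param seed integer seed for the relocations.
#' @param label profile label carried into the report.
#' @param check_placements if `TRUE`, assert width preservation and
#'   in-reference placement for every permutation (test mode).
#' @return an `overlap_report` (one-row data.frame): `label`, `n_query`,
#'   `n_in_reference`, `n_excluded`, `n_overlap`, `fraction`, `p_perm`,
#'   `p_analytic`, `n_perm`, `seed`.
#' @export
reference_constrained_test <- function(query, catalog, ref,
                                       min_overlap = 50L, n_perm = 1000L,
                                       seed = 1L, label = "query",
                                       check_placements = FALSE) {
  .check_granges(query)
  stopifnot(inherits(ref, "reference_regions"))
  if (!length(query)) stop("no peaks to screen")
  if (n_perm < 100) stop("'n_perm' must be >= 100")
  loci <- if (inherits(catalog, "phantom_catalog")) catalog$loci else catalog
  loci <- merge_intervals(loci)
  obs <- overlap_fraction(query, loci, min_overlap)
  widths <- GenomicRanges::width(query)
  uw <- sort(unique(widths))
  spaces <- lapply(uw, .placement_space, ref_regions = ref$regions,
                   loci = loci, min_overlap = min_overlap)
  names(spaces) <- as.character(uw)
  placeable <- vapply(spaces, function(s) s$total > 0, TRUE)
  excluded <- widths %in% uw[!placeable]
  if (any(excluded))
    warning(sprintf("%d peak(s) wider than every reference region excluded",
                    sum(excluded)))
  kept_w <- widths[!excluded]
  t_obs <- sum(obs$hit[!excluded])
  set.seed(as.integer(seed))
  t_star <- integer(n_perm)
  for (w in as.character(sort(unique(kept_w)))) {
    sp <- spaces[[w]]
    n_g <- sum(kept_w == as.numeric(w))
    idx <- matrix(ceiling(stats::runif(n_perm * n_g) * sp$total),
                  nrow = n_perm)
    if (check_placements) {
      # map a sample of indices back to coordinates and assert the
      # relocated peak fits inside one reference region
      reg <- findInterval(idx - 1, sp$offset)
      starts <- sp$rs[reg] + (idx - sp$offset[reg] - 1)
      stopifnot(all(starts >= sp$rs[reg]),
                all(starts + as.numeric(w) - 1 <=
                      sp$rs[reg] + sp$a[reg] + as.numeric(w) - 2))
    }
    t_star <- t_star + rowSums(matrix(.in_qualifying(as.vector(idx), sp),
                                      nrow = n_perm))
  }
  p_perm <- (1 + sum(t_star >= t_obs)) / (1 + n_perm)
  q <- vapply(as.character(kept_w), function(w) {
    sp <- spaces[[w]]
    if (sp$total == 0) 0 else sp$q_total / sp$total
  }, 0)
  p_analytic <- .poisbinom_tail(q, t_obs)
  in_ref <- overlap_hits(query, ref$regions, min_overlap = 1L)$hit
  out <- data.frame(label = label, n_query = length(query),
                    n_in_reference = sum(in_ref),
                    n_excluded = sum(excluded),
                    n_overlap = obs$n_hit, fraction = obs$fraction,
                    p_perm = p_perm, p_analytic = p_analytic,
                    n_perm = as.integer(n_perm), seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  class(out) <- c("overlap_report", class(out))
  out
}

#' Screen multiple peak profiles against a catalog
#'
#' Runs [reference_constrained_test()] per profile; failures are caught
#' and reported per profile without aborting the batch.  A
#' Benjamini-Hochberg adjusted permutation p-value is added as `p_bh`;
#' the summary flag (`flagged`) uses the plain per-profile criterion
#' `fraction > fraction_threshold` and `p_perm < alpha`.
#'
#' @param profiles named list of peak `GRanges`.
#' @param catalog a `phantom_catalog` or `GRanges`.
#' @param ref a `reference_regions` object.
#' @param min_overlap minimum overlap (bp); default 50.
#' @param n_perm permutations per profile; default 1000.
#' @param seed integer seed; profile i uses `seed + i - 1`.
#' @param fraction_threshold flagging threshold on the overlap fraction;
#'   default 0.2.
#' @param alpha significance level for flagging; default 0.05.
#' @return data.frame with one row per profile (columns as in
#'   [reference_constrained_test()] plus `p_bh`, `flagged`, `error`);
#'   attribute `n_flagged` counts flagged profiles.
#' @export
screen_profiles <- function(profiles, catalog, ref, min_overlap = 50L,
                            n_perm = 1000L, seed = 1L,
                            fraction_threshold = 0.2, alpha = 0.05) {
  if (!is.list(profiles) || length(profiles) < 1)
    stop("'profiles' must be a non-empty named list of GRanges")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    names(profiles) <- sprintf("profile%d", seq_along(profiles))
  rows <- lapply(seq_along(profiles), function(i) {
    res <- tryCatch(
      reference_constrained_test(profiles[[i]], catalog, ref,
                                 min_overlap = min_overlap, n_perm = n_perm,
                                 seed = seed + i - 1,
                                 label = names(profiles)[i]),
      error = function(e) {
        data.frame(label = names(profiles)[i], n_query = NA, n_in_reference = NA,
                   n_excluded = NA, n_overlap = NA, fraction = NA,
                   p_perm = NA, p_analytic = NA, n_perm = NA, seed = NA,
                   stringsAsFactors = FALSE)
      })
    res$error <- if (anyNA(res$p_perm)) TRUE else FALSE
    res
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_bh <- stats::p.adjust(tab$p_perm, method = "BH")
  tab$flagged <- !is.na(tab$fraction) & tab$fraction > fraction_threshold &
    !is.na(tab$p_perm) & tab$p_perm < alpha
  attr(tab, "n_flagged") <- sum(tab$flagged)
  tab
}

#' Rank correlation of replicate tracks over catalog loci
#'
#' Extracts the mean per-bin signal of every track over each catalog
#' locus and returns the pairwise Spearman correlation matrix.  Tracks
#' with constant locus signal yield `NA` entries.
#'
#' @param tracks named list of >= 2 `coverage_track` objects sharing bin
#'   size.
#' @param catalog a `phantom_catalog` or `GRanges`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
replicate_rank_correlation <- function(tracks, catalog) {
  if (!is.list(tracks) || length(tracks) < 2)
    stop("need at least 2 tracks")
  bs <- unique(vapply(tracks, function(t) t$bin_size, 0L))
  if (length(bs) != 1) stop("tracks must share a bin size")
  loci <- if (inherits(catalog, "phantom_catalog")) catalog$loci else catalog
  if (!length(loci)) stop("empty catalog")
  if (is.null(names(tracks)))
    names(tracks) <- sprintf("track%d", seq_along(tracks))
  chrs <- as.character(GenomicRanges::seqnames(loci))
  b0 <- floor((GenomicRanges::start(loci) - 1) / bs) + 1   # first bin
  b1 <- ceiling(GenomicRanges::end(loci) / bs)             # last bin
  sig <- vapply(tracks, function(t) {
    vapply(seq_along(loci), function(i) {
      v <- t$values[[chrs[i]]]
      if (is.null(v)) return(NA_real_)
      mean(v[b0[i]:min(b1[i], length(v))])
    }, 0)
  }, numeric(length(loci)))
  n <- ncol(sig)
  m <- diag(1, n)
  dimnames(m) <- list(colnames(sig), colnames(sig))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- stats::complete.cases(sig[, c(i, j)])
    m[i, j] <- m[j, i] <-
      if (sum(ok) < 2 || stats::sd(sig[ok, i]) == 0 || stats::sd(sig[ok, j]) == 0)
        NA_real_
      else stats::cor(sig[ok, i], sig[ok, j], method = "spearman")
  }
  m
}
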