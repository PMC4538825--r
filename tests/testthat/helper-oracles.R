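# Brute-force per-base oracles for the interval kernel, plus random
# instance generators.  Oracles work on a 0-based half-open boolean mask
# over a small chromosome and are independent of the GRanges code path.

# build a GRanges from 0-based half-open coordinates (the BED convention
# used by the oracles)
gr0 <- function(chrom, start0, end0, ...) {
  genomic_intervals(chrom, start0 + 1, end0, ...)
}

# per-base boolean mask (length L) of a GRanges restricted to one chromosome
mask_of <- function(gr, chrom, L) {
  m <- logical(L)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  for (i in seq_along(gr)) {
    s0 <- GenomicRanges::start(gr)[i] - 1
    e0 <- GenomicRanges::end(gr)[i]
    m[(s0 + 1):min(e0, L)] <- TRUE
  }
  m
}

# extract maximal TRUE runs of a mask as a data.frame of 0-based half-open
# intervals
runs_of <- function(m) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start0 = starts[r$values], end0 = ends[r$values])
}

# GRanges as a 0-based half-open data.frame for comparisons
as_df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1,
             end0 = GenomicRanges::end(gr))
}

# random interval set on one chromosome of length L (0-based half-open)
random_set <- function(n, L, max_w = 200) {
  s0 <- sample.int(L - 1, n, replace = TRUE) - 1
  w <- sample.int(max_w, n, replace = TRUE)
  gr0(rep("chrT", n), s0, pmin(L, s0 + w))
}

# all-pairs overlap oracle: for each query, is there a subject interval
# sharing >= min_overlap bases (0-based half-open inputs as data.frames)
pairs_hit_oracle <- function(q, s, min_overlap) {
  vapply(seq_len(nrow(q)), function(i) {
    ov <- pmin(q$end0[i], s$end0) - pmax(q$start0[i], s$start0)
    any(ov >= min_overlap & q$chrom[i] == s$chrom)
  }, TRUE)
}
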