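## Catalog characterization: where do the loci sit relative to gene
## models (promoter / TTS / exon / intron / intergenic), how does their
## prevalence track promoter activity, and how do they co-occur with
## histone-mark and transcription-factor peak sets.
##
## Feature assignment is midpoint-based with the fixed priority
## promoter > TTS > exon > intron > intergenic, so the category fractions
## partition to one.  Promoter means TSS +/- promoter_halfwidth.

#' Assign each peak to a genomic feature category
#'
#' Assignment uses the peak midpoint.  Ties between genes in the same
#' category are broken by smaller absolute distance to the TSS, then by
#' lexicographic gene id.  Intergenic peaks carry the distance to the
#' nearest TSS and no gene id.
#'
#' @param peaks a `GRanges`.
#' @param models a `gene_models` object.
#' @param promoter_halfwidth promoter window half-width around the TSS
#'   (bp); default 1000.
#' @param tts_halfwidth TTS window half-width (bp); default 1000.
#' @return data.frame with one row per peak: `category`, `gene_id`,
#'   `distance_to_tss` (signed, midpoint - TSS).
#' @export
assign_feature <- function(peaks, models, promoter_halfwidth = 1000L,
                           tts_halfwidth = 1000L) {
  .check_granges(peaks)
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  if (!nrow(g)) stop("'models' contains no genes")
  mids <- interval_midpoints(peaks)
  chrs <- as.character(GenomicRanges::seqnames(peaks))
  ex_chr <- as.character(GenomicRanges::seqnames(models$exons))
  ex_gid <- S4Vectors::mcols(models$exons)$gene_id
  gene_tss <- stats::setNames(g$tss, g$gene_id)
  out <- data.frame(category = character(length(peaks)),
                    gene_id = NA_character_,
                    distance_to_tss = NA_real_, stringsAsFactors = FALSE)
  # candidate gene pick for a midpoint within a window set
  pick <- function(cand_gid, dist) {
    o <- order(abs(dist), cand_gid)
    c(cand_gid[o[1]], dist[o[1]])
  }
  for (i in seq_along(peaks)) {
    on_chr <- g$chrom == chrs[i]
    gi <- g[on_chr, , drop = FALSE]
    if (!nrow(gi)) {
      out$category[i] <- "intergenic"
      next
    }
    d_tss <- mids[i] - gi$tss
    d_tts <- mids[i] - gi$tts
    in_prom <- abs(d_tss) <= promoter_halfwidth
    in_tts <- abs(d_tts) <= tts_halfwidth
    if (any(in_prom)) {
      p <- pick(gi$gene_id[in_prom], d_tss[in_prom])
      out$category[i] <- "promoter"
    } else if (any(in_tts)) {
      p <- pick(gi$gene_id[in_tts], d_tss[in_tts])
      out$category[i] <- "TTS"
    } else {
      ei <- which(ex_chr == chrs[i] &
                    GenomicRanges::start(models$exons) <= mids[i] &
                    GenomicRanges::end(models$exons) >= mids[i])
      in_tx <- gi$tx_start <= mids[i] & gi$tx_end >= mids[i]
      if (length(ei)) {
        cand <- unique(ex_gid[ei])
        p <- pick(cand, mids[i] - gene_tss[cand])
        out$category[i] <- "exon"
      } else if (any(in_tx)) {
        p <- pick(gi$gene_id[in_tx], d_tss[in_tx])
        out$category[i] <- "intron"
      } else {
        out$category[i] <- "intergenic"
        out$distance_to_tss[i] <- d_tss[which.min(abs(d_tss))]
        next
      }
    }
    out$gene_id[i] <- p[1]
    out$distance_to_tss[i] <- as.numeric(p[2])
  }
  out
}

#' Feature-category distribution of a catalog
#'
#' @param catalog a `phantom_catalog` or `GRanges`.
#' @param models a `gene_models` object.
#' @param promoter_halfwidth,tts_halfwidth window half-widths (bp).
#' @return named numeric vector of fractions over
#'   promoter/TTS/exon/intron/intergenic, summing to 1.
#' @export
feature_distribution <- function(catalog, models, promoter_halfwidth = 1000L,
                                 tts_halfwidth = 1000L) {
  loci <- if (inherits(catalog, "phantom_catalog")) catalog$loci else catalog
  if (!length(loci)) stop("empty catalog")
  asg <- assign_feature(loci, models, promoter_halfwidth, tts_halfwidth)
  cats <- c("promoter", "TTS", "exon", "intron", "intergenic")
  counts <- table(factor(asg$category, levels = cats))
  stats::setNames(as.numeric(counts) / length(loci), cats)
}

#' Fraction of catalog loci inside TSS windows
#'
#' Counts loci whose midpoint falls in the merged union of
#' `window_total`-wide windows centered at every TSS (default 4 kb, the
#' reference-region definition of the screening test).
#'
#' @param catalog a `phantom_catalog` or `GRanges`.
#' @param models a `gene_models` object.
#' @param window_total total window width (bp); default 4000.
#' @return fraction in `[0, 1]`.
#' @export
tss_window_fraction <- function(catalog, models, window_total = 4000L) {
  loci <- if (inherits(catalog, "phantom_catalog")) catalog$loci else catalog
  if (!length(loci)) stop("empty catalog")
  win <- merge_intervals(windows_around_points(tss_points(models), window_total))
  mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(loci),
                                 IRanges::IRanges(interval_midpoints(loci),
                                                  width = 1L))
  mean(overlap_hits(mids, win, min_overlap = 1L)$hit)
}

#' Phantom-peak prevalence by promoter-strength quintile
#'
#' Genes with expression values are ranked and split into five groups of
#' (near-)equal size, remainder genes going to the lower-expression
#' groups.  For each group the fraction of genes whose promoter window
#' contains at least one catalog-locus midpoint is returned, together
#' with the group mean expression.  Genes without expression are
#' excluded and tallied.
#'
#' @param models a `gene_models` object.
#' @param expr named expression vector (see [read_expression()]).
#' @param catalog a `phantom_catalog` or `GRanges`.
#' @param promoter_halfwidth promoter half-width (bp); default 1000.
#' @return list with `prevalence` (5 fractions, lowest to highest
#'   expression), `mean_expression` (5 values), `group_size` (5 counts)
#'   and `n_excluded`.
#' @export
expression_quintile_prevalence <- function(models, expr, catalog,
                                           promoter_halfwidth = 1000L) {
  stopifnot(inherits(models, "gene_models"))
  loci <- if (inherits(catalog, "phantom_catalog")) catalog$loci else catalog
  g <- models$genes
  has_expr <- g$gene_id %in% names(expr)
  n_excluded <- sum(!has_expr)
  g <- g[has_expr, , drop = FALSE]
  if (nrow(g) < 5) stop("need expression for at least 5 genes")
  e <- unname(expr[g$gene_id])
  o <- order(e, g$gene_id)   # deterministic tie-break by gene id
  g <- g[o, , drop = FALSE]; e <- e[o]
  n <- nrow(g)
  base <- n %/% 5L; extra <- n %% 5L
  sizes <- base + (seq_len(5L) <= extra)
  grp <- rep(seq_len(5L), sizes)
  mids <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(loci),
    IRanges::IRanges(interval_midpoints(loci), width = 1L))
  prom <- windows_around_points(
    data.frame(chrom = g$chrom, pos = g$tss),
    total_width = 2L * promoter_halfwidth)
  # promoter = |midpoint - TSS| <= halfwidth, symmetric about the TSS
  # base, matching assign_feature()
  GenomicRanges::end(prom) <- GenomicRanges::end(prom) + 1L
  gene_hit <- overlap_hits(prom, mids, min_overlap = 1L)$hit
  list(prevalence = as.numeric(tapply(gene_hit, grp, mean)),
       mean_expression = as.numeric(tapply(e, grp, mean)),
       group_size = as.integer(sizes),
       n_excluded = n_excluded)
}

#' Binary overlap matrix of catalog loci against labeled mark sets
#'
#' Entry (locus, mark) is 1 when the locus overlaps the mark set by at
#' least `min_overlap` bp (the binary scoring scheme used for histone
#' modification peak sets); column means give per-mark prevalence.
#'
#' @param catalog a `phantom_catalog` or `GRanges`.
#' @param mark_sets named list of `GRanges`.
#' @param min_overlap minimum overlap (bp); default 1.
#' @return integer 0/1 matrix, loci in rows, marks in columns.
#' @export
binary_mark_matrix <- function(catalog, mark_sets, min_overlap = 1L) {
  loci <- if (inherits(catalog, "phantom_catalog")) catalog$loci else catalog
  if (!length(loci)) stop("empty catalog")
  if (!is.list(mark_sets) || is.null(names(mark_sets)) ||
      any(!nzchar(names(mark_sets))))
    stop("'mark_sets' must be a named list of GRanges")
  m <- vapply(mark_sets, function(s)
    as.integer(overlap_hits(loci, s, min_overlap)$hit),
    integer(length(loci)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(loci),
                                   dimnames = list(NULL, names(mark_sets)))
  m
}

#' Transcription-factor co-binding profile and HOT fraction
#'
#' Counts, per catalog locus, the number of distinct transcription-factor
#' peak sets overlapping it (>= 1 bp), returns the normalized histogram
#' of counts and the fraction of loci exceeding `hot_threshold`
#' ("High Occupancy Target" regions: more than 8 distinct factors under
#' the default).
#'
#' @param catalog a `phantom_catalog` or `GRanges`.
#' @param tf_sets named list of `GRanges` with distinct labels.
#' @param hot_threshold count above which a locus is HOT; default 8.
#' @return list with `counts` (per locus), `histogram` (named fractions
#'   over 0..max count) and `hot_fraction`.
#' @export
tf_count_profile <- function(catalog, tf_sets, hot_threshold = 8L) {
  loci <- if (inherits(catalog, "phantom_catalog")) catalog$loci else catalog
  if (!length(loci)) stop("empty catalog")
  if (!is.list(tf_sets) || length(tf_sets) < 1)
    stop("'tf_sets' must be a non-empty named list")
  if (is.null(names(tf_sets)) || anyDuplicated(names(tf_sets)))
    stop("'tf_sets' labels must be unique and non-empty")
  mat <- binary_mark_matrix(loci, tf_sets, min_overlap = 1L)
  counts <- rowSums(mat)
  hist <- table(factor(counts, levels = 0:max(counts)))
  list(counts = counts,
       histogram = as.numeric(hist) / length(loci),
       hot_fraction = mean(counts > hot_threshold))
}
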