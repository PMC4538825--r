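## Synthetic study generator.  Emulates the statistical structure the
## analysis assumes: a genome of non-overlapping genes with log-normal
## expression; a subset of "sticky" promoters whose propensity rises with
## expression rank and which appear as peaks in every antibody and every
## genotype; genuine binding loci per factor that vanish in the
## antigen-null mutant; replicate peak sets with center jitter, dropout
## and uniform background false peaks; Poisson coverage with planted
## high-read-density regions; and DamID probe tracks with score shifts at
## target loci.  All ground truth is retained so recovery can be graded.
##
## All randomness flows from one root seed; each stage draws from a child
## seed obtained by stable string hashing of the stage name, so stages
## are reproducible independently of each other.

# deterministic 31-bit child seed from root seed + stage name
child_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(paste0(stage, ":", seed)))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Configuration of the synthetic study
#'
#' Defaults define the package's reference desk-scale study: one 2-Mb
#' chromosome, 500 genes, two antibodies ("factors") with three
#' replicates each, 200-bp peaks, 20-bp replicate jitter, 10% replicate
#' dropout, 5 background false peaks per Mb, 10 reads per 25-bp bin
#' (~0.8 million reads per library), 1% of genes carrying a planted
#' high-read-density region at 10x input depth, and DamID probes every
#' 100 bp.
#'
#' @param seed root seed; fixes every downstream draw.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param n_genes total genes.
#' @param expr_meanlog,expr_sdlog log-normal expression parameters.
#' @param sticky_intercept,sticky_slope logistic sticky-propensity
#'   coefficients on the expression-rank percentile in (0, 1):
#'   P(sticky) = plogis(intercept + slope * percentile).
#' @param n_genuine_per_factor genuine binding loci per factor.
#' @param factors factor (antibody) labels.
#' @param peak_width peak width (bp).
#' @param replicate_jitter_sd replicate center jitter SD (bp).
#' @param replicate_dropout per-replicate peak dropout probability.
#' @param background_peak_rate background false peaks per Mb per replicate.
#' @param coverage_depth mean input reads per bin.
#' @param chip_fold fold enrichment of ChIP coverage over peak loci.
#' @param bin_size coverage bin size (bp).
#' @param hdr_gene_fraction fraction of genes carrying a planted HDR.
#' @param hdr_fold input-depth multiplier inside HDRs.
#' @param damid_probe_spacing DamID probe spacing (bp).
#' @param damid_shift score shift for probes inside target loci (SD units).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_chroms = 1L, chrom_length = 2e6,
                             n_genes = 500L, expr_meanlog = 1,
                             expr_sdlog = 1, sticky_intercept = -2,
                             sticky_slope = 2.5,
                             n_genuine_per_factor = 100L,
                             factors = c("factorA", "factorB"),
                             peak_width = 200L, replicate_jitter_sd = 20,
                             replicate_dropout = 0.1,
                             background_peak_rate = 5,
                             coverage_depth = 10, chip_fold = 10,
                             bin_size = 25L, hdr_gene_fraction = 0.01,
                             hdr_fold = 10, damid_probe_spacing = 100L,
                             damid_shift = 4) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              sticky_intercept = sticky_intercept,
              sticky_slope = sticky_slope,
              n_genuine_per_factor = as.integer(n_genuine_per_factor),
              factors = factors, peak_width = as.integer(peak_width),
              replicate_jitter_sd = replicate_jitter_sd,
              replicate_dropout = replicate_dropout,
              background_peak_rate = background_peak_rate,
              coverage_depth = coverage_depth, chip_fold = chip_fold,
              bin_size = as.integer(bin_size),
              hdr_gene_fraction = hdr_gene_fraction, hdr_fold = hdr_fold,
              damid_probe_spacing = as.integer(damid_probe_spacing),
              damid_shift = damid_shift)
  probs <- c(replicate_dropout = replicate_dropout,
             hdr_gene_fraction = hdr_gene_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (cfg$chrom_length / cfg$n_chroms / max(1L, cfg$n_genes) < 3000)
    stop("infeasible gene density: genes do not fit without overlap")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic world with planted ground truth
#'
#' Genes are placed without overlap (one per uniform slot with jittered
#' offset), expression is log-normal, each gene becomes sticky with a
#' logistic propensity in its expression-rank percentile, sticky loci are
#' fixed-width intervals centered at the TSS, genuine loci per factor are
#' drawn uniformly away from sticky loci, and HDR loci are 2-kb windows
#' at a random subset of non-sticky genes.
#'
#' @param cfg a [synthetic_config()].
#' @return an object of class `synthetic_truth`: list with `models`
#'   (a `gene_models`), `expression` (named vector), `sticky_loci`
#'   (`GRanges` with `gene_id`), `genuine_loci` (named list of `GRanges`
#'   per factor), `hdr_loci` (`GRanges`), `chrom_sizes`, `config`.
#' @export
generate_world <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(child_seed(cfg$seed, "world"))
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  genes <- list(); exons <- list()
  gid <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    n <- per_chrom[ci]
    if (!n) next
    slot <- cfg$chrom_length / n
    tx_len <- round(stats::runif(n, 500, min(2500, slot - 600)))
    margin <- 250
    offset <- round(stats::runif(n, margin, slot - tx_len - margin))
    tx_start <- round((seq_len(n) - 1) * slot) + offset + 1   # 1-based
    tx_end <- tx_start + tx_len - 1
    strand <- sample(c("+", "-"), n, replace = TRUE)
    for (k in seq_len(n)) {
      gid <- gid + 1L
      id <- sprintf("g%04d", gid)
      n_ex <- sample(1:3, 1)
      if (n_ex == 1) {
        ex_s <- tx_start[k]; ex_e <- tx_end[k]
      } else {
        # 2*(n_ex - 1) interior cuts -> exon/intron/.../exon
        cuts <- sort(sample(seq(tx_start[k] + 50, tx_end[k] - 50),
                            2 * (n_ex - 1)))
        bounds <- c(tx_start[k], cuts, tx_end[k])
        ex_s <- bounds[seq(1, length(bounds), by = 2)]
        ex_e <- bounds[seq(2, length(bounds), by = 2)]
      }
      genes[[gid]] <- data.frame(gene_id = id, chrom = chroms[ci],
                                 strand = strand[k],
                                 tx_start = tx_start[k], tx_end = tx_end[k],
                                 stringsAsFactors = FALSE)
      exons[[gid]] <- data.frame(gene_id = id, chrom = chroms[ci],
                                 start = ex_s, end = ex_e)
    }
  }
  genes <- do.call(rbind, genes)
  exdf <- do.call(rbind, exons)
  models <- .build_gene_models(
    genes,
    GenomicRanges::GRanges(exdf$chrom,
                           IRanges::IRanges(exdf$start, exdf$end),
                           gene_id = exdf$gene_id),
    path = "<synthetic>")
  g <- models$genes
  expr <- stats::setNames(stats::rlnorm(nrow(g), cfg$expr_meanlog,
                                        cfg$expr_sdlog), g$gene_id)
  pct <- (rank(expr, ties.method = "first") - 0.5) / length(expr)
  p_sticky <- stats::plogis(cfg$sticky_intercept + cfg$sticky_slope * pct)
  is_sticky <- stats::rbinom(nrow(g), 1, p_sticky) == 1
  w <- cfg$peak_width
  sticky <- GenomicRanges::GRanges(
    g$chrom[is_sticky],
    IRanges::IRanges(pmax(1, g$tss[is_sticky] - floor(w / 2)), width = w),
    gene_id = g$gene_id[is_sticky])
  sticky <- GenomicRanges::sort(sticky, ignore.strand = TRUE)
  # genuine loci per factor: uniform centers, disjoint from sticky loci
  # and from each other within a factor
  genuine <- list()
  for (f in cfg$factors) {
    found <- GenomicRanges::GRanges()
    guard <- 0
    while (length(found) < cfg$n_genuine_per_factor) {
      guard <- guard + 1
      if (guard > 200) stop("cannot place genuine loci; genome too crowded")
      need <- cfg$n_genuine_per_factor - length(found)
      chr <- sample(chroms, 2 * need + 10, replace = TRUE)
      center <- round(stats::runif(length(chr), w, cfg$chrom_length - w))
      cand <- GenomicRanges::GRanges(
        chr, IRanges::IRanges(center - floor(w / 2), width = w))
      bad <- overlap_hits(cand, sticky, 1L)$hit |
        (length(found) > 0 & overlap_hits(cand, found, 1L)$hit)
      cand <- cand[!bad]
      # drop mutual overlaps among the new candidates, keeping the first
      if (length(cand) > 1) {
        keep <- !logical(length(cand))
        ov <- GenomicRanges::findOverlaps(cand, cand, ignore.strand = TRUE)
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        keep[qh[qh > sh]] <- FALSE
        cand <- cand[keep]
      }
      found <- suppressWarnings(c(found, cand))
      if (length(found) > cfg$n_genuine_per_factor)
        found <- found[seq_len(cfg$n_genuine_per_factor)]
    }
    found <- GenomicRanges::sort(found, ignore.strand = TRUE)
    S4Vectors::mcols(found)$name <- sprintf("%s_genuine%d", f, seq_along(found))
    genuine[[f]] <- found
  }
  n_hdr <- max(1L, round(cfg$hdr_gene_fraction * nrow(g)))
  non_sticky_idx <- which(!is_sticky)
  hdr_genes <- sample(non_sticky_idx, min(n_hdr, length(non_sticky_idx)))
  hdr <- GenomicRanges::GRanges(
    g$chrom[hdr_genes],
    IRanges::IRanges(pmax(1, g$tss[hdr_genes] - 1000L), width = 2000L))
  hdr <- merge_intervals(hdr)
  structure(list(models = models, expression = expr, sticky_loci = sticky,
                 genuine_loci = genuine, hdr_loci = hdr,
                 chrom_sizes = chrom_sizes, config = cfg),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_truth: %d genes on %d chromosome(s) (%.3g bp), ",
    "%d sticky loci, %s genuine loci, %d HDR regions\n"),
    nrow(x$models$genes), length(x$chrom_sizes), sum(x$chrom_sizes),
    length(x$sticky_loci),
    paste(vapply(x$genuine_loci, length, 0L), collapse = "+"),
    length(x$hdr_loci)))
  invisible(x)
}

#' Simulate replicate peak sets for one factor and genotype
#'
#' Wild-type replicates contain sticky plus genuine loci; antigen-null
#' mutant replicates contain sticky loci only.  Every emitted peak center
#' is jittered, peaks drop out independently per replicate, and uniform
#' background false peaks are added.  Sticky/genuine peaks score higher
#' than background.
#'
#' @param truth a `synthetic_truth`.
#' @param cfg the matching [synthetic_config()] (defaults to
#'   `truth$config`).
#' @param genotype `"WT"` or `"mutant"`.
#' @param factor factor label (must exist in the truth).
#' @param n_replicates number of replicates; default 3.
#' @return list of peak `GRanges` (with `score`, `name`), one per
#'   replicate.
#' @export
simulate_peak_sets <- function(truth, cfg = truth$config,
                               genotype = c("WT", "mutant"),
                               factor = cfg$factors[1], n_replicates = 3L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  genotype <- match.arg(genotype)
  if (!factor %in% names(truth$genuine_loci))
    stop("unknown factor: ", factor)
  set.seed(child_seed(cfg$seed, paste("peaks", genotype, factor)))
  base <- if (genotype == "WT") {
    suppressWarnings(c(GenomicRanges::granges(truth$sticky_loci),
                       GenomicRanges::granges(truth$genuine_loci[[factor]])))
  } else GenomicRanges::granges(truth$sticky_loci)
  w <- cfg$peak_width
  centers <- interval_midpoints(base)
  chrs <- as.character(GenomicRanges::seqnames(base))
  genome_mb <- sum(truth$chrom_sizes) / 1e6
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    keep <- stats::runif(length(base)) >= cfg$replicate_dropout
    c_k <- round(centers[keep] +
                   stats::rnorm(sum(keep), 0, cfg$replicate_jitter_sd))
    scores <- pmax(2, stats::rnorm(sum(keep), 10, 2))
    n_bg <- stats::rpois(1, cfg$background_peak_rate * genome_mb)
    bg_chr <- sample(names(truth$chrom_sizes), n_bg, replace = TRUE)
    bg_c <- round(stats::runif(n_bg, w, sum(truth$chrom_sizes) /
                                 length(truth$chrom_sizes) - w))
    chrom <- c(chrs[keep], bg_chr)
    cent <- c(c_k, bg_c)
    score <- c(scores, pmax(0.5, stats::rnorm(n_bg, 3, 0.5)))
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(pmax(1, cent - floor(w / 2)), width = w),
      score = score)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    S4Vectors::mcols(gr)$name <- sprintf("%s_%s_rep%d_p%d", factor, genotype,
                                         r, seq_along(gr))
    out[[r]] <- gr
  }
  names(out) <- sprintf("%s_%s_rep%d", factor, genotype, seq_len(n_replicates))
  out
}

#' Simulate a binned coverage track
#'
#' Per-bin Poisson counts.  Input tracks have mean `coverage_depth`
#' everywhere except planted HDR bins at `hdr_fold` times the depth;
#' ChIP tracks additionally gain `chip_fold * coverage_depth` over the
#' genotype's peak loci (sticky plus, for WT, the factor's genuine loci).
#'
#' @param truth a `synthetic_truth`.
#' @param cfg the matching [synthetic_config()].
#' @param role `"chip"` or `"input"`.
#' @param genotype `"WT"` or `"mutant"` (used for `role = "chip"`).
#' @param factor factor label (used for `role = "chip"`).
#' @return a `coverage_track`.
#' @export
simulate_coverage <- function(truth, cfg = truth$config,
                              role = c("input", "chip"),
                              genotype = c("WT", "mutant"),
                              factor = cfg$factors[1]) {
  stopifnot(inherits(truth, "synthetic_truth"))
  role <- match.arg(role)
  genotype <- match.arg(genotype)
  set.seed(child_seed(cfg$seed, paste("coverage", role, genotype, factor)))
  bs <- cfg$bin_size
  values <- list()
  peak_loci <- if (role == "chip") {
    if (genotype == "WT")
      suppressWarnings(c(GenomicRanges::granges(truth$sticky_loci),
                         GenomicRanges::granges(truth$genuine_loci[[factor]])))
    else GenomicRanges::granges(truth$sticky_loci)
  } else GenomicRanges::GRanges()
  for (chr in names(truth$chrom_sizes)) {
    n_bins <- ceiling(truth$chrom_sizes[[chr]] / bs)
    lambda <- rep(cfg$coverage_depth, n_bins)
    mark_bins <- function(gr) {
      gi <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
      if (!length(gi)) return(integer(0))
      unlist(mapply(function(s, e) {
        (floor((s - 1) / bs) + 1):min(n_bins, ceiling(e / bs))
      }, GenomicRanges::start(gi), GenomicRanges::end(gi),
      SIMPLIFY = FALSE))
    }
    hb <- mark_bins(truth$hdr_loci)
    lambda[hb] <- lambda[hb] * cfg$hdr_fold
    if (length(peak_loci)) {
      pb <- mark_bins(peak_loci)
      lambda[pb] <- lambda[pb] + cfg$chip_fold * cfg$coverage_depth
    }
    values[[chr]] <- if (cfg$coverage_depth == 0) numeric(n_bins)
                     else stats::rpois(n_bins, lambda)
  }
  coverage_track(values, bs,
                 label = paste(role, genotype, factor, sep = "_"))
}

#' Simulate a DamID probe table
#'
#' Probes tiled every `damid_probe_spacing` bp score N(0, 1), shifted by
#' `damid_shift` inside the target loci.
#'
#' @param truth a `synthetic_truth`.
#' @param cfg the matching [synthetic_config()].
#' @param target_loci `GRanges` of loci where the profiled protein binds.
#' @return data.frame with `chrom`, `pos` (1-based), `score`, `probe_id`.
#' @export
simulate_damid <- function(truth, cfg = truth$config,
                           target_loci = GenomicRanges::GRanges()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (cfg$damid_probe_spacing < 1) stop("probe spacing must be positive")
  set.seed(child_seed(cfg$seed, "damid"))
  tabs <- lapply(names(truth$chrom_sizes), function(chr) {
    pos <- seq(floor(cfg$damid_probe_spacing / 2), truth$chrom_sizes[[chr]],
               by = cfg$damid_probe_spacing)
    data.frame(chrom = chr, pos = pos, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab$score <- stats::rnorm(nrow(tab))
  if (length(target_loci)) {
    pgr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$pos, width = 1L))
    inside <- overlap_hits(pgr, target_loci, 1L)$hit
    tab$score[inside] <- tab$score[inside] + cfg$damid_shift
  }
  tab$probe_id <- sprintf("probe%06d", seq_len(nrow(tab)))
  tab
}

#' Write the gene models of a synthetic truth as the TSV dialect
#'
#' @param models a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  ex_gid <- S4Vectors::mcols(models$exons)$gene_id
  ex_by <- split(seq_along(models$exons), ex_gid)
  starts0 <- vapply(g$gene_id, function(id)
    paste(GenomicRanges::start(models$exons)[ex_by[[id]]] - 1, collapse = ","), "")
  ends0 <- vapply(g$gene_id, function(id)
    paste(GenomicRanges::end(models$exons)[ex_by[[id]]], collapse = ","), "")
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                    txStart = g$tx_start - 1, txEnd = g$tx_end,
                    exonStarts = starts0, exonEnds = ends0)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression vector as the two-column TSV
#' @param expr named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(data.frame(gene_id = names(expr), expression = unname(expr)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
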