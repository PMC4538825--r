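## Readers/writers for the plain-text formats the pipeline touches.
## File formats are 0-based half-open (BED, bedGraph, the TSV gene dialect,
## DamID probe positions); everything is converted to 1-based closed GRanges
## coordinates on load and back on write.  Readers validate strictly and
## reject malformed records with the file name and line number -- silent
## repair of structural problems is a classic source of empty overlaps.

.read_lines_nocomment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

.parse_fail <- function(path, lineno, why) {
  stop(sprintf("%s, line %d: %s", path, lineno, why), call. = FALSE)
}

#' Read a BED file of peaks or regions
#'
#' Accepts BED3/BED5/BED6.  Coordinates are converted from 0-based
#' half-open to the internal 1-based closed convention.  Comment, `track`
#' and `browser` lines are skipped; unsorted input is sorted on load.
#' Chromosome names are taken verbatim (no "chr" stripping or adding).
#'
#' @param path path to a BED file.
#' @return a sorted `GRanges` with metadata columns `name` and `score`
#'   when present.
#' @export
read_bed <- function(path) {
  lc <- .read_lines_nocomment(path)
  if (!length(lc$lines))
    return(GenomicRanges::GRanges())
  fields <- strsplit(lc$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    .parse_fail(path, lc$lineno[which(nf < 3)[1]], "fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    .parse_fail(path, lc$lineno[bad[1]], "non-numeric start/end")
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad))
    .parse_fail(path, lc$lineno[bad[1]],
                sprintf("invalid interval [%s, %s)", start0[bad[1]], end0[bad[1]]))
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  score <- ifelse(nf >= 5,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[min(5L, length(f))], ""))),
                  NA_real_)
  strand <- rep("*", length(chrom))
  if (any(nf >= 6)) {
    s6 <- vapply(fields, function(f) if (length(f) >= 6) f[[6L]] else "*", "")
    strand <- ifelse(s6 %in% c("+", "-"), s6, "*")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  if (any(nf >= 4)) S4Vectors::mcols(gr)$name <- name
  if (any(nf >= 5)) S4Vectors::mcols(gr)$score <- score
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write intervals to a BED file
#'
#' Writes BED with as many of the optional `name`, `score`, strand columns
#' as are present, preceded by a provenance comment header.
#'
#' @param s a `GRanges`, optionally with `name` and `score` metadata.
#' @param path output path.
#' @param provenance character vector written as `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_bed <- function(s, path, provenance = NULL) {
  .check_granges(s)
  mc <- S4Vectors::mcols(s)
  cols <- list(
    as.character(GenomicRanges::seqnames(s)),
    format(GenomicRanges::start(s) - 1, scientific = FALSE, trim = TRUE),
    format(GenomicRanges::end(s), scientific = FALSE, trim = TRUE)
  )
  has_name <- "name" %in% names(mc)
  has_score <- "score" %in% names(mc)
  strands <- as.character(GenomicRanges::strand(s))
  has_strand <- any(strands != "*")
  if (has_name || has_score || has_strand)
    cols <- c(cols, list(if (has_name) as.character(mc$name)
                         else sprintf("r%d", seq_along(s))))
  if (has_score || has_strand)
    cols <- c(cols, list(if (has_score) as.character(mc$score) else "0"))
  if (has_strand) cols <- c(cols, list(strands))
  con <- file(path, "w")
  on.exit(close(con))
  header <- c(sprintf("# %s", pp_version()), provenance)
  writeLines(paste0("# ", sub("^# ?", "", header)), con)
  if (length(s))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

## ---- coverage tracks -------------------------------------------------

#' Construct a binned coverage track
#'
#' A coverage track holds one numeric vector of non-negative per-bin
#' values per chromosome, a common bin size, and a library label.
#'
#' @param values named list of numeric vectors (one per chromosome).
#' @param bin_size bin width in bp.
#' @param label library label.
#' @return an object of class `coverage_track` with fields `values`,
#'   `bin_size`, `label`, `total_signal`.
#' @export
coverage_track <- function(values, bin_size = 25L, label = "track") {
  if (!is.list(values) || is.null(names(values)) || any(names(values) == ""))
    stop("'values' must be a named list of per-chromosome numeric vectors")
  if (any(vapply(values, function(v) any(v < 0 | !is.finite(v)), TRUE)))
    stop("coverage values must be finite and >= 0")
  if (bin_size < 1) stop("'bin_size' must be >= 1")
  structure(
    list(values = lapply(values, as.numeric),
         bin_size = as.integer(bin_size),
         label = label,
         total_signal = sum(vapply(values, sum, 0))),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s': %d chromosome(s), bin %d bp, total %.4g\n",
              x$label, length(x$values), x$bin_size, x$total_signal))
  invisible(x)
}

#' Chromosome lengths spanned by a coverage track
#' @param t a `coverage_track`.
#' @return named numeric vector of lengths (bp).
#' @export
track_chrom_sizes <- function(t) {
  stopifnot(inherits(t, "coverage_track"))
  vapply(t$values, length, 0L) * t$bin_size
}

#' Read a bedGraph file into a binned coverage track
#'
#' Record values are interpreted as per-base densities; each record
#' contributes `value * overlap_length / bin_size` to every bin it
#' touches, so re-binning conserves the length-weighted total signal.
#' Overlapping records and negative values are rejected.
#'
#' @param path path to a bedGraph file (0-based half-open records).
#' @param bin_size target bin width (bp), default 25.
#' @param chrom_sizes optional named chromosome lengths; otherwise inferred
#'   from the furthest record end, rounded up to a full bin.
#' @return a `coverage_track`.
#' @export
read_bedgraph <- function(path, bin_size = 25L, chrom_sizes = NULL) {
  lc <- .read_lines_nocomment(path)
  if (!length(lc$lines))
    return(coverage_track(stats::setNames(list(), character(0)),
                          bin_size, label = basename(path)))
  fields <- strsplit(lc$lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4))
    .parse_fail(path, lc$lineno[which(nf < 4)[1]], "fewer than 4 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- as.numeric(vapply(fields, `[[`, "", 2L))
  end0 <- as.numeric(vapply(fields, `[[`, "", 3L))
  val <- as.numeric(vapply(fields, `[[`, "", 4L))
  bad <- which(is.na(start0) | is.na(end0) | is.na(val))
  if (length(bad)) .parse_fail(path, lc$lineno[bad[1]], "non-numeric field")
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad)) .parse_fail(path, lc$lineno[bad[1]], "invalid interval")
  bad <- which(val < 0)
  if (length(bad)) .parse_fail(path, lc$lineno[bad[1]], "negative value")
  values <- list()
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    o <- i[order(start0[i])]
    if (any(end0[o][-length(o)] > start0[o][-1]))
      stop(sprintf("%s: overlapping bedGraph records on %s", path, chr),
           call. = FALSE)
    len <- if (!is.null(chrom_sizes)) {
      if (is.na(chrom_sizes[chr]))
        stop("chromosome missing from 'chrom_sizes': ", chr)
      chrom_sizes[[chr]]
    } else ceiling(max(end0[o]) / bin_size) * bin_size
    n_bins <- ceiling(len / bin_size)
    v <- numeric(n_bins)
    for (j in o) {
      b0 <- floor(start0[j] / bin_size)   # first touched bin, 0-based
      b1 <- ceiling(end0[j] / bin_size) - 1
      for (b in b0:b1) {
        ov <- min(end0[j], (b + 1) * bin_size) - max(start0[j], b * bin_size)
        v[b + 1] <- v[b + 1] + val[j] * ov / bin_size
      }
    }
    values[[chr]] <- v
  }
  coverage_track(values, bin_size, label = basename(path))
}

#' Write a coverage track as bedGraph
#' @param t a `coverage_track`.
#' @param path output path.
#' @param provenance optional header comment lines.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(t, path, provenance = NULL) {
  stopifnot(inherits(t, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", sub("^# ?", "", c(pp_version(), provenance))), con)
  for (chr in names(t$values)) {
    v <- t$values[[chr]]
    if (!length(v)) next
    start0 <- (seq_along(v) - 1) * t$bin_size
    keep <- v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.10g", chr, start0[keep],
                         start0[keep] + t$bin_size, v[keep]), con)
  }
  invisible(path)
}

#' Read a fixed-step wiggle file
#'
#' Supports `fixedStep chrom=<chr> start=<pos> step=<n> [span=<n>]`
#' declaration lines with one value per following line; `span`, when
#' given, must equal `step` (non-overlapping bins).  The step becomes the
#' track bin size and must be shared by all blocks.
#'
#' @param path path to a wiggle file.
#' @return a `coverage_track` with `bin_size` equal to the step.
#' @export
read_fixedstep_wig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  values <- list()
  bin_size <- NULL
  chr <- NULL; at <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^(#|track\\b)", ln)) next
    if (grepl("^fixedStep", ln)) {
      kv <- regmatches(ln, gregexpr("\\w+=\\S+", ln))[[1]]
      kvs <- strsplit(kv, "=", fixed = TRUE)
      m <- stats::setNames(vapply(kvs, `[[`, "", 2L), vapply(kvs, `[[`, "", 1L))
      if (!all(c("chrom", "start", "step") %in% names(m)))
        .parse_fail(path, i, "fixedStep needs chrom=, start=, step=")
      step <- as.integer(m["step"])
      if ("span" %in% names(m) && as.integer(m["span"]) != step)
        .parse_fail(path, i, "span must equal step")
      if (is.null(bin_size)) bin_size <- step
      else if (bin_size != step) .parse_fail(path, i, "inconsistent step")
      chr <- unname(m["chrom"])
      start1 <- as.integer(m["start"])          # wiggle is 1-based
      if ((start1 - 1) %% step != 0)
        .parse_fail(path, i, "start not aligned to step")
      at <- (start1 - 1) %/% step + 1           # bin index, 1-based
      if (is.null(values[[chr]])) values[[chr]] <- numeric(0)
    } else {
      if (is.null(chr)) .parse_fail(path, i, "value before fixedStep header")
      v <- suppressWarnings(as.numeric(ln))
      if (is.na(v)) .parse_fail(path, i, "non-numeric value")
      if (v < 0) .parse_fail(path, i, "negative value")
      cur <- values[[chr]]
      if (at > length(cur)) cur <- c(cur, numeric(at - length(cur)))
      cur[at] <- v
      values[[chr]] <- cur
      at <- at + 1
    }
  }
  if (is.null(bin_size)) stop(path, ": no fixedStep blocks found")
  coverage_track(values, bin_size, label = basename(path))
}

#' Scale a coverage track to a target library size
#'
#' Multiplies every bin by one scalar so that the total signal equals
#' `target_total` (the study convention is size-normalizing libraries to
#' one million reads).
#'
#' @param t a `coverage_track` with positive total signal.
#' @param target_total desired total signal (reads), default 1e6.
#' @return a rescaled `coverage_track`.
#' @export
normalize_track <- function(t, target_total = 1e6) {
  stopifnot(inherits(t, "coverage_track"))
  if (t$total_signal <= 0) stop("cannot normalize a track with zero total signal")
  if (target_total <= 0) stop("'target_total' must be > 0")
  f <- target_total / t$total_signal
  coverage_track(lapply(t$values, `*`, f), t$bin_size, t$label)
}

## ---- gene models, expression, DamID probes ---------------------------

#' Read gene models from a TSV dialect or a simplified GTF
#'
#' The TSV dialect has columns `gene_id`, `chrom`, `strand`, `txStart`,
#' `txEnd`, `exonStarts`, `exonEnds` (0-based half-open; exon start/end
#' lists comma-separated).  Files whose name ends in `.gtf` are parsed as
#' a GTF2 subset: `exon` feature rows with a `gene_id "..."` attribute,
#' 1-based inclusive coordinates (converted on load).  The TSS is the
#' transcript start on `+` genes and the transcript end on `-` genes.
#'
#' @param path path to the gene-model file.
#' @return an object of class `gene_models`: list with `genes` (data.frame
#'   `gene_id`, `chrom`, `strand`, `tss`, `tts`, `tx_start`, `tx_end`;
#'   1-based closed) and `exons` (`GRanges` with a `gene_id` column).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gtf$", path, ignore.case = TRUE))
    return(.gene_models_from_gtf(path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd",
            "exonStarts", "exonEnds")
  if (!all(need %in% names(tab)))
    stop(path, ": gene TSV must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop(path, ": duplicate gene_id: ",
         tab$gene_id[anyDuplicated(tab$gene_id)])
  ex_list <- mapply(function(gid, chr, s0, e0) {
    starts <- as.numeric(strsplit(s0, ",")[[1]])
    ends <- as.numeric(strsplit(e0, ",")[[1]])
    if (!length(starts) || length(starts) != length(ends))
      stop(path, ": gene ", gid, " has no parsable exons")
    data.frame(gene_id = gid, chrom = chr, start0 = starts, end0 = ends)
  }, tab$gene_id, tab$chrom, tab$exonStarts, tab$exonEnds, SIMPLIFY = FALSE)
  ex <- do.call(rbind, ex_list)
  .build_gene_models(
    data.frame(gene_id = tab$gene_id, chrom = tab$chrom, strand = tab$strand,
               tx_start = tab$txStart + 1, tx_end = tab$txEnd,
               stringsAsFactors = FALSE),
    GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start0 + 1, ex$end0),
                           gene_id = ex$gene_id),
    path
  )
}

.gene_models_from_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    .parse_fail(path, which(keep)[which(nf < 9)[1]], "fewer than 9 GTF columns")
  feat <- vapply(fields, `[[`, "", 3L)
  ex <- fields[feat == "exon"]
  if (!length(ex)) stop(path, ": no exon features found")
  gid <- vapply(ex, function(f) {
    m <- regmatches(f[[9L]], regexec('gene_id "([^"]+)"', f[[9L]]))[[1]]
    if (length(m) < 2) stop(path, ": exon without gene_id attribute")
    m[2]
  }, "")
  chrom <- vapply(ex, `[[`, "", 1L)
  start1 <- as.numeric(vapply(ex, `[[`, "", 4L))   # GTF is 1-based inclusive
  end1 <- as.numeric(vapply(ex, `[[`, "", 5L))
  strand <- vapply(ex, `[[`, "", 7L)
  genes <- do.call(rbind, lapply(split(seq_along(gid), gid), function(i) {
    if (length(unique(chrom[i])) != 1 || length(unique(strand[i])) != 1)
      stop(path, ": gene ", gid[i[1]], " spans chromosomes or strands")
    data.frame(gene_id = gid[i[1]], chrom = chrom[i[1]], strand = strand[i[1]],
               tx_start = min(start1[i]), tx_end = max(end1[i]),
               stringsAsFactors = FALSE)
  }))
  .build_gene_models(
    genes,
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1), gene_id = gid),
    path
  )
}

.build_gene_models <- function(genes, exons, path) {
  if (!all(genes$strand %in% c("+", "-")))
    stop(path, ": gene strand must be '+' or '-'")
  if (any(genes$tx_end < genes$tx_start))
    stop(path, ": gene with txEnd <= txStart: ",
         genes$gene_id[which(genes$tx_end < genes$tx_start)[1]])
  n_ex <- table(S4Vectors::mcols(exons)$gene_id)
  missing_ex <- setdiff(genes$gene_id, names(n_ex))
  if (length(missing_ex))
    stop(path, ": gene without exons: ", missing_ex[1])
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  genes$tts <- ifelse(genes$strand == "+", genes$tx_end, genes$tx_start)
  rownames(genes) <- NULL
  exons <- GenomicRanges::sort(exons, ignore.strand = TRUE)
  structure(list(genes = genes[, c("gene_id", "chrom", "strand", "tss", "tts",
                                   "tx_start", "tx_end")],
                 exons = exons),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), length(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' TSS table of a gene-model set
#' @param models a `gene_models` object.
#' @return data.frame with `chrom`, `pos` (1-based TSS), `strand`, `gene_id`.
#' @export
tss_points <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  data.frame(chrom = models$genes$chrom, pos = models$genes$tss,
             strand = models$genes$strand, gene_id = models$genes$gene_id,
             stringsAsFactors = FALSE)
}

#' Read a two-column expression table
#'
#' TSV with header columns `gene_id` and `expression` (arbitrary
#' non-negative units, e.g. RPKM; downstream analyses use only ranks).
#'
#' @param path path to the TSV file.
#' @return named numeric vector of expression values keyed by gene id.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene_id", "expression") %in% names(tab)))
    stop(path, ": expression TSV must have columns gene_id, expression")
  if (anyDuplicated(tab$gene_id))
    stop(path, ": duplicate gene_id in expression table")
  if (any(!is.finite(tab$expression) | tab$expression < 0))
    stop(path, ": expression values must be finite and >= 0")
  stats::setNames(tab$expression, tab$gene_id)
}

#' Read a DamID probe table
#'
#' TSV with header columns `chrom`, `pos` (0-based probe coordinate),
#' `score` and optionally `probe_id`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `chrom`, `pos` (1-based), `score`,
#'   `probe_id`.
#' @export
read_damid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("chrom", "pos", "score") %in% names(tab)))
    stop(path, ": DamID TSV must have columns chrom, pos, score")
  if (any(tab$pos < 0)) stop(path, ": negative probe position")
  if (any(!is.finite(tab$score))) stop(path, ": non-finite probe score")
  data.frame(chrom = tab$chrom, pos = tab$pos + 1, score = tab$score,
             probe_id = if ("probe_id" %in% names(tab)) tab$probe_id
                        else sprintf("probe%d", seq_len(nrow(tab))),
             stringsAsFactors = FALSE)
}

#' Write a DamID probe table
#' @param probes data.frame as returned by [read_damid()] (1-based `pos`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_damid <- function(probes, path) {
  out <- data.frame(chrom = probes$chrom, pos = probes$pos - 1,
                    score = probes$score, probe_id = probes$probe_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
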