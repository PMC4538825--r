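# Format readers/writers: conversion at the 0-based/1-based boundary,
# strict validation with file+line errors, and conservation properties.

test_that("read_bed converts BED coordinates and keeps name/score", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment", "track name=x",
               "chr2L\t100\t300\tp1\t7.5"), p)
  gr <- read_bed(p)
  expect_equal(GenomicRanges::start(gr), 101)   # 0-based 100 -> 1-based 101
  expect_equal(GenomicRanges::end(gr), 300)
  expect_equal(S4Vectors::mcols(gr)$name, "p1")
  expect_equal(S4Vectors::mcols(gr)$score, 7.5)
})

test_that("read_bed rejects malformed records with the line number", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2L\t100\t300", "chr2L\t300\t100"), p)
  expect_error(read_bed(p), "line 2")
  writeLines(c("chr2L\t100"), p)
  expect_error(read_bed(p), "3 columns")
  writeLines(c("chr2L\tx\t300"), p)
  expect_error(read_bed(p), "non-numeric")
})

test_that("BED write/read round-trip is the identity on records", {
  set.seed(9)
  n <- 1000
  s0 <- sample.int(1e6, n)
  gr <- gr0(sample(c("chr2L", "chr3R", "chrX"), n, replace = TRUE),
            s0, s0 + sample.int(500, n, replace = TRUE),
            name = sprintf("p%04d", 1:n),
            score = round(stats::runif(n, 0, 100), 3))
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, p, provenance = "round-trip test")
  back <- read_bed(p)
  expect_identical(as_df0(back), as_df0(gr))
  expect_identical(S4Vectors::mcols(back)$name, S4Vectors::mcols(gr)$name)
  expect_equal(S4Vectors::mcols(back)$score, S4Vectors::mcols(gr)$score)
})

test_that("read_bedgraph re-bins with length weighting and validates", {
  p <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t200\t3.0", p)
  tr <- read_bedgraph(p, bin_size = 100)
  expect_equal(tr$values$chr1, c(3, 3))
  expect_equal(tr$total_signal, 6)        # 3.0 * 200 bp / 100 bp-per-bin
  # partial bin split
  writeLines("chr1\t50\t150\t4.0", p)
  tr2 <- read_bedgraph(p, bin_size = 100)
  expect_equal(tr2$values$chr1, c(2, 2))
  # overlapping records rejected
  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t1"), p)
  expect_error(read_bedgraph(p), "overlapping")
  writeLines("chr1\t0\t100\t-1", p)
  expect_error(read_bedgraph(p), "negative")
  # empty file
  writeLines("# nothing", p)
  expect_equal(read_bedgraph(p)$total_signal, 0)
})

test_that("bedGraph total signal is conserved for random records", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 50
    starts <- sort(sample(seq(0, 99000, by = 10), n))
    ends <- starts + sample(10:900, n, replace = TRUE)
    ends <- pmin(ends, c(starts[-1], 100000))  # non-overlapping
    keep <- ends > starts
    vals <- round(stats::runif(sum(keep), 0, 50), 3)
    p <- withr::local_tempfile(fileext = ".bedgraph")
    writeLines(sprintf("chrU\t%d\t%d\t%g", starts[keep], ends[keep], vals), p)
    tr <- read_bedgraph(p, bin_size = 25)
    expect_equal(tr$total_signal,
                 sum(vals * (ends[keep] - starts[keep])) / 25,
                 tolerance = 1e-9)
  }
})

test_that("write_bedgraph/read_bedgraph round-trips a binned track", {
  set.seed(4)
  tr <- coverage_track(list(chrA = rpois(400, 5), chrB = rpois(200, 2)), 25)
  p <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, p)
  back <- read_bedgraph(p, bin_size = 25,
                        chrom_sizes = track_chrom_sizes(tr))
  expect_equal(back$values, tr$values)
})

test_that("read_fixedstep_wig parses blocks and enforces structure", {
  p <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=25 span=25",
               "1.5", "2", "0", "4"), p)
  tr <- read_fixedstep_wig(p)
  expect_equal(tr$bin_size, 25)
  expect_equal(tr$values$chr1, c(1.5, 2, 0, 4))
  writeLines(c("fixedStep chrom=chr1 start=1 step=25 span=10", "1"), p)
  expect_error(read_fixedstep_wig(p), "span")
  writeLines(c("3.0"), p)
  expect_error(read_fixedstep_wig(p), "before fixedStep")
})

test_that("normalize_track rescales to the target preserving shape", {
  tr <- coverage_track(list(c1 = c(2, 4, 6), c2 = c(8, 0)), 25)
  nt <- normalize_track(tr, 10)
  expect_equal(nt$total_signal, 10)
  expect_equal(nt$values$c1 / tr$values$c1, rep(0.5, 3))
  # identity at the current total
  expect_equal(normalize_track(tr, tr$total_signal)$values, tr$values)
  # ratio of any two bins preserved
  set.seed(2)
  tr2 <- coverage_track(list(c1 = stats::runif(100, 1, 10)), 25)
  nt2 <- normalize_track(tr2, 1e6)
  expect_equal(nt2$values$c1[3] / nt2$values$c1[77],
               tr2$values$c1[3] / tr2$values$c1[77])
  expect_error(normalize_track(coverage_track(list(c1 = c(0, 0)), 25)),
               "zero total")
})

test_that("gene-model TSV gives strand-aware TSS and intron structure", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds",
    "gplus\tchr1\t+\t1000\t2000\t1000,1800\t1200,2000",
    "gminus\tchr1\t-\t1000\t2000\t1000,1800\t1200,2000"), p)
  gm <- read_gene_models(p)
  g <- gm$genes
  expect_equal(g$tss[g$gene_id == "gplus"], 1001)   # 0-based 1000
  expect_equal(g$tts[g$gene_id == "gplus"], 2000)
  expect_equal(g$tss[g$gene_id == "gminus"], 2000)  # minus strand: tx end
  ex <- gm$exons[S4Vectors::mcols(gm$exons)$gene_id == "gplus"]
  expect_equal(GenomicRanges::start(ex), c(1001, 1801))
  # the intron is the exon gap [1200, 1800) in 0-based terms
  gaps <- IRanges::gaps(IRanges::IRanges(GenomicRanges::start(ex),
                                         GenomicRanges::end(ex)))
  gaps <- gaps[IRanges::start(gaps) > 1]
  expect_equal(IRanges::start(gaps) - 1, 1200)
  expect_equal(IRanges::end(gaps), 1800)
  # duplicate gene ids rejected
  writeLines(c(
    "gene_id\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds",
    "g\tchr1\t+\t0\t100\t0\t100",
    "g\tchr1\t+\t200\t300\t200\t300"), p)
  expect_error(read_gene_models(p), "duplicate")
})

test_that("simplified GTF is converted from 1-based inclusive", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr2L", "src", "exon", "1001", "2000", ".", "+", ".",
          'gene_id "gA";', sep = "\t")), p)
  gm <- read_gene_models(p)
  expect_equal(gm$genes$tx_start, 1001)   # internal 1-based == GTF start
  expect_equal(gm$genes$tx_end, 2000)
  expect_equal(gm$genes$tss, 1001)
  # as 0-based half-open this is [1000, 2000)
  expect_equal(as_df0(gm$exons)[, c("start0", "end0")],
               data.frame(start0 = 1000, end0 = 2000))
})

test_that("gene-model round-trip through the TSV writer is the identity", {
  truth <- generate_world(synthetic_config(seed = 5, n_genes = 40,
                                           chrom_length = 2e5))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(truth$models, p)
  back <- read_gene_models(p)
  expect_equal(back$genes, truth$models$genes)
  expect_equal(as_df0(back$exons), as_df0(truth$models$exons))
})

test_that("expression and DamID tables validate and convert", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\texpression", "g1\t5.5", "g2\t0"), p)
  e <- read_expression(p)
  expect_equal(unname(e["g1"]), 5.5)
  writeLines(c("gene_id\texpression", "g1\t-2"), p)
  expect_error(read_expression(p), ">= 0")
  writeLines(c("chrom\tpos\tscore", "chr1\t100\t1.5"), p)
  d <- read_damid(p)
  expect_equal(d$pos, 101)   # 0-based input position
  writeLines(c("chrom\tpos\tscore", "chr1\t-5\t1"), p)
  expect_error(read_damid(p), "negative")
})
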