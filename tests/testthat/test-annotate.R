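# Annotation: midpoint-based feature assignment under the fixed priority
# promoter > TTS > exon > intron > intergenic, expression-quintile
# prevalence, binary mark matrices and the HOT profile.

two_gene_models <- function() {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(
    "gene_id\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds",
    # gene A: + strand, TSS at 0-based 10000, intron [10500, 13500)
    "geneA\tc\t+\t10000\t14000\t10000,13500\t10500,14000",
    # gene B: + strand far away
    "geneB\tc\t+\t50000\t52000\t50000\t52000"), p)
  read_gene_models(p)
}

test_that("assign_feature follows the category priority at midpoints", {
  gm <- two_gene_models()
  # midpoint exactly at geneA's TSS
  at_tss <- gr0("c", 9900, 10100)
  a <- assign_feature(at_tss, gm)
  expect_equal(a$category, "promoter")
  expect_equal(a$gene_id, "geneA")
  expect_equal(a$distance_to_tss, 0)
  # midpoint 5 kb from every gene
  far <- gr0("c", 29900, 30100)
  expect_equal(assign_feature(far, gm)$category, "intergenic")
  expect_true(is.na(assign_feature(far, gm)$gene_id))
  # intronic midpoint (outside promoter/TTS windows): geneA intron center
  intr <- gr0("c", 11900, 12100)
  expect_equal(assign_feature(intr, gm)$category, "intron")
  # TTS window beats exon/intron
  at_tts <- gr0("c", 13900, 14100)
  expect_equal(assign_feature(at_tts, gm)$category, "TTS")
  # promoter window wins over everything when both apply: a midpoint in
  # geneB's promoter that also lies in geneB's exon
  in_prom_exon <- gr0("c", 50400, 50600)
  expect_equal(assign_feature(in_prom_exon, gm)$category, "promoter")
})

test_that("feature fractions partition to one and respect extremes", {
  gm <- two_gene_models()
  catalog <- gr0(rep("c", 4), c(9900, 11900, 29900, 50400),
                 c(10100, 12100, 30100, 50600))
  fd <- feature_distribution(catalog, gm)
  expect_equal(sum(fd), 1, tolerance = 1e-9)
  expect_equal(unname(fd["promoter"]), 0.5)
  expect_equal(unname(fd["intron"]), 0.25)
  expect_equal(unname(fd["intergenic"]), 0.25)
  # an all-TSS catalog is all-promoter
  at_tss <- gr0(c("c", "c"), c(9900, 49900), c(10100, 50100))
  expect_equal(unname(feature_distribution(at_tss, gm)["promoter"]), 1)
  expect_equal(tss_window_fraction(at_tss, gm), 1)
  # all-intergenic
  expect_equal(unname(feature_distribution(
    gr0("c", 29900, 30100), gm)["promoter"]), 0)
})

test_that("every locus gets exactly one category regardless of order", {
  truth <- generate_world(synthetic_config(seed = 61, n_genes = 80,
                                           chrom_length = 3e5))
  set.seed(62)
  catalog <- random_set(60, 3e5)
  GenomicRanges::seqnames(catalog)
  catalog <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(
                                      GenomicRanges::start(catalog),
                                      GenomicRanges::end(catalog)))
  a1 <- assign_feature(catalog, truth$models)
  expect_true(all(a1$category %in%
                    c("promoter", "TTS", "exon", "intron", "intergenic")))
  perm <- sample(length(catalog))
  a2 <- assign_feature(catalog[perm], truth$models)
  expect_equal(a2$category, a1$category[perm])
  fd <- feature_distribution(catalog, truth$models)
  expect_equal(sum(fd), 1, tolerance = 1e-9)
})

test_that("expression quintiles are equal-sized and prevalence localizes", {
  truth <- generate_world(synthetic_config(seed = 63, n_genes = 103,
                                           chrom_length = 6e5))
  g <- truth$models$genes
  expr <- truth$expression
  # plant catalog loci only at the promoters of the top quintile
  o <- order(unname(expr[g$gene_id]), g$gene_id)
  top <- g[tail(o, 20), ]
  catalog <- GenomicRanges::GRanges(top$chrom,
                                    IRanges::IRanges(top$tss, width = 1))
  q <- expression_quintile_prevalence(truth$models, expr, catalog)
  expect_equal(sum(q$group_size), 103)
  expect_true(all(abs(q$group_size - 103 / 5) <= 1))
  expect_equal(q$prevalence[1:4], rep(0, 4))
  expect_gt(q$prevalence[5], 0)
  expect_true(all(diff(q$mean_expression) > 0))
  # genes without expression are excluded and tallied
  q2 <- expression_quintile_prevalence(truth$models, expr[1:50], catalog)
  expect_equal(q2$n_excluded, nrow(g) - 50)
})

test_that("uniform planting gives near-uniform quintile prevalence", {
  truth <- generate_world(synthetic_config(seed = 64, n_genes = 500))
  g <- truth$models$genes
  set.seed(65)
  rate <- 0.4
  hit_genes <- g[runif(nrow(g)) < rate, ]
  catalog <- GenomicRanges::GRanges(hit_genes$chrom,
                                    IRanges::IRanges(hit_genes$tss, width = 1))
  q <- expression_quintile_prevalence(truth$models, truth$expression, catalog)
  # each quintile prevalence is a Binomial(100, 0.4) proportion
  ci <- stats::qbinom(c(0.0005, 0.9995), 100, rate) / 100
  expect_true(all(q$prevalence >= ci[1] & q$prevalence <= ci[2]))
})

test_that("binary_mark_matrix scores overlaps 0/1 against each set", {
  catalog <- gr0(rep("c", 3), c(0, 1000, 2000), c(200, 1200, 2200))
  m <- binary_mark_matrix(catalog,
                          list(all = catalog, none = gr0("c", 9000, 9100)))
  expect_equal(unname(m[, "all"]), rep(1L, 3))
  expect_equal(unname(m[, "none"]), rep(0L, 3))
  set.seed(66)
  marks <- list(m1 = random_set(20, 5000), m2 = random_set(5, 5000))
  loci <- merge_intervals(random_set(30, 5000))
  mm <- binary_mark_matrix(loci, marks, min_overlap = 10)
  for (lbl in names(marks))
    expect_equal(unname(mm[, lbl]),
                 as.integer(pairs_hit_oracle(as_df0(loci),
                                             as_df0(marks[[lbl]]), 10)))
})

test_that("tf_count_profile counts distinct factors and flags HOT loci", {
  locus <- gr0("c", 1000, 1200)
  one <- list(tf1 = gr0("c", 900, 1300))
  p1 <- tf_count_profile(locus, one)
  expect_equal(p1$histogram, c(0, 1))   # all loci have count 1
  expect_equal(p1$hot_fraction, 0)
  # 10 factors over one locus: 10 > 8 -> HOT
  ten <- setNames(lapply(1:10, function(i) gr0("c", 900, 1300)),
                  sprintf("tf%d", 1:10))
  p10 <- tf_count_profile(locus, ten, hot_threshold = 8)
  expect_equal(p10$hot_fraction, 1)
  # exactly 8 factors is not HOT (strictly more than the threshold)
  eight <- ten[1:8]
  expect_equal(tf_count_profile(locus, eight)$hot_fraction, 0)
  expect_error(tf_count_profile(locus, c(one, one)), "unique")
  # random sets vs per-locus label-count oracle
  set.seed(67)
  tfs <- setNames(lapply(1:6, function(i) random_set(15, 8000)),
                  sprintf("f%d", 1:6))
  loci <- merge_intervals(random_set(25, 8000))
  prof <- tf_count_profile(loci, tfs)
  want <- rowSums(vapply(tfs, function(s)
    pairs_hit_oracle(as_df0(loci), as_df0(s), 1), logical(length(loci))))
  expect_equal(unname(prof$counts), unname(want))
})
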