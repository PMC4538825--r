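# Reference-constrained overlap test: degenerate cases, exact analytic
# probabilities vs full enumeration, seed reproducibility, monotonicity,
# and batch screening.

make_ref_world <- function(seed = 101, n_genes = 120, chrom_length = 6e5) {
  truth <- generate_world(synthetic_config(seed = seed, n_genes = n_genes,
                                           chrom_length = chrom_length))
  list(truth = truth,
       ref = reference_regions(truth$models, 4000),
       catalog = build_catalog(list(sticky = truth$sticky_loci)))
}

test_that("overlap_fraction matches a brute-force scan and handles extremes", {
  w <- make_ref_world()
  expect_equal(overlap_fraction(w$catalog$loci, w$catalog)$fraction, 1)
  far <- gr0(rep("zzz", 5), seq(0, 4000, by = 1000),
             seq(200, 4200, by = 1000))
  expect_equal(overlap_fraction(far, w$catalog)$fraction, 0)
  expect_error(overlap_fraction(GenomicRanges::GRanges(), w$catalog),
               "no peaks")
  set.seed(3)
  for (rep in 1:10) {
    q <- random_set(40, 20000)
    s <- merge_intervals(random_set(40, 20000))
    got <- overlap_fraction(q, s, 25)$fraction
    expect_equal(got, mean(pairs_hit_oracle(as_df0(q), as_df0(s), 25)))
  }
})

test_that("query equal to catalog loci attains the maximal statistic", {
  w <- make_ref_world()
  q <- w$catalog$loci[1:20]
  r <- reference_constrained_test(q, w$catalog, w$ref, min_overlap = 50,
                                  n_perm = 999, seed = 5,
                                  check_placements = TRUE)
  expect_equal(r$n_overlap, 20)
  expect_equal(r$fraction, 1)
  expect_equal(r$p_perm, 1 / 1000)
})

test_that("catalog disjoint from the reference gives null T* and p 1", {
  w <- make_ref_world()
  empty_cat <- gr0("chr_far", 0, 200)
  q <- gr0("chr_other", 0, 200)
  r <- reference_constrained_test(q, empty_cat, w$ref, n_perm = 200, seed = 2)
  expect_equal(r$n_overlap, 0)
  expect_equal(r$p_perm, 1)
  expect_equal(r$p_analytic, 1)
})

test_that("identical seeds reproduce p_perm; p is monotone in T", {
  w <- make_ref_world()
  q <- c(w$catalog$loci[1:10], w$ref$regions[1:30])
  S4Vectors::mcols(q) <- NULL
  q <- GenomicRanges::resize(q, 200, fix = "center")
  r1 <- reference_constrained_test(q, w$catalog, w$ref, n_perm = 300, seed = 9)
  r2 <- reference_constrained_test(q, w$catalog, w$ref, n_perm = 300, seed = 9)
  expect_identical(r1$p_perm, r2$p_perm)
  # adding hits (holding everything else fixed) cannot raise p
  q_more <- c(w$catalog$loci[1:25], w$ref$regions[1:15])
  S4Vectors::mcols(q_more) <- NULL
  q_more <- GenomicRanges::resize(q_more, 200, fix = "center")
  r3 <- reference_constrained_test(q_more, w$catalog, w$ref, n_perm = 300,
                                   seed = 9)
  expect_gte(r3$n_overlap, r1$n_overlap)
  expect_lte(r3$p_perm, r1$p_perm)
  expect_lte(r3$p_analytic, r1$p_analytic)
})

test_that("p_analytic equals exhaustive enumeration on a small instance", {
  # one 500 bp reference region, one catalog locus, uniform width 60
  ref <- as_reference_regions(gr0("c", 0, 500))
  cat <- gr0("c", 100, 200)
  sp <- phantomPeaks:::.placement_space(ref$regions, 60, cat, 30)
  allowed <- 500 - 60 + 1
  expect_equal(sp$total, allowed)
  # enumerate every allowed 0-based start
  ok <- vapply(0:(allowed - 1), function(s0) {
    min(s0 + 60, 200) - max(s0, 100) >= 30
  }, TRUE)
  expect_equal(sp$q_total / sp$total, mean(ok))
  # binomial tail at q for a 5-peak uniform-width query
  q5 <- gr0(rep("c", 5), c(90, 120, 300, 400, 10), c(150, 180, 360, 460, 70))
  r <- reference_constrained_test(q5, cat, ref, min_overlap = 30,
                                  n_perm = 2000, seed = 4)
  expect_equal(r$p_analytic,
               sum(stats::dbinom(r$n_overlap:5, 5, mean(ok))))
  # permutation agrees with analytic within Monte-Carlo error
  se <- sqrt(r$p_analytic * (1 - r$p_analytic) / 2000)
  expect_lt(abs(r$p_perm - r$p_analytic), 4 * se + 1e-3)
})

test_that("mixed query widths use the exact Poisson-binomial tail", {
  ref <- as_reference_regions(gr0(c("c", "c"), c(0, 2000), c(1000, 2600)))
  cat <- gr0(c("c", "c"), c(200, 2100), c(500, 2300))
  q <- gr0(rep("c", 4), c(150, 700, 2050, 2400), c(250, 900, 2250, 2500))
  r <- reference_constrained_test(q, cat, ref, min_overlap = 40,
                                  n_perm = 4000, seed = 6)
  # independent oracle: per-width enumeration + convolution
  qs <- vapply(unique(GenomicRanges::width(q)), function(w) {
    hits <- 0; tot <- 0
    for (reg in list(c(0, 1000), c(2000, 2600))) {
      for (s0 in reg[1]:(reg[2] - w)) {
        tot <- tot + 1
        ov <- max(min(s0 + w, 500) - max(s0, 200),
                  min(s0 + w, 2300) - max(s0, 2100))
        if (ov >= 40) hits <- hits + 1
      }
    }
    hits / tot
  }, 0)
  names(qs) <- as.character(unique(GenomicRanges::width(q)))
  p_each <- qs[as.character(GenomicRanges::width(q))]
  f <- 1
  for (pi in p_each) f <- c(f * (1 - pi), 0) + c(0, f * pi)
  expect_equal(r$p_analytic, sum(f[(r$n_overlap + 1):length(f)]))
  se <- sqrt(r$p_analytic * (1 - r$p_analytic) / 4000)
  expect_lt(abs(r$p_perm - r$p_analytic), 4 * se + 1e-3)
})

test_that("peaks wider than every reference region are excluded", {
  ref <- as_reference_regions(gr0("c", 0, 300))
  cat <- gr0("c", 50, 150)
  q <- gr0(c("c", "c"), c(10, 0), c(110, 1000))   # second peak width 1000
  expect_warning(
    r <- reference_constrained_test(q, cat, ref, min_overlap = 20,
                                    n_perm = 200, seed = 1),
    "excluded")
  expect_equal(r$n_excluded, 1)
})

test_that("screen_profiles reports per-profile fractions, BH and flags", {
  w <- make_ref_world()
  profiles <- list(
    self = w$catalog$loci,
    none = gr0(rep("nowhere", 10), seq(0, 9000, by = 1000),
               seq(200, 9200, by = 1000)))
  tab <- screen_profiles(profiles, w$catalog, w$ref, n_perm = 200, seed = 3)
  expect_equal(tab$fraction, c(1, 0))
  expect_equal(tab$label, c("self", "none"))
  expect_true(all(tab$p_bh >= tab$p_perm - 1e-12))
  expect_equal(attr(tab, "n_flagged"), 1)
  expect_false(any(tab$error))
  # per-profile failure does not abort the batch
  tab2 <- screen_profiles(list(ok = w$catalog$loci,
                               broken = GenomicRanges::GRanges()),
                          w$catalog, w$ref, n_perm = 200, seed = 3)
  expect_false(tab2$error[1])
  expect_true(tab2$error[2])
})

test_that("planted overlap fractions are recovered by screening", {
  w <- make_ref_world(seed = 55, n_genes = 150, chrom_length = 7e5)
  loci <- w$catalog$loci
  n <- 40
  set.seed(17)
  planted <- c(0, 0.25, 0.5, 0.75, 1)
  profiles <- lapply(planted, function(f) {
    k <- round(f * n)
    hits <- if (k) GenomicRanges::resize(sample(loci, k), 200, fix = "center")
            else GenomicRanges::GRanges()
    miss <- if (k < n) {
      gr0(rep("decoy", n - k),
          seq(0, by = 1000, length.out = n - k),
          seq(200, by = 1000, length.out = n - k))
    } else GenomicRanges::GRanges()
    g <- suppressWarnings(c(hits, miss))
    S4Vectors::mcols(g) <- NULL
    g
  })
  names(profiles) <- sprintf("f%.2f", planted)
  tab <- screen_profiles(profiles, w$catalog, w$ref, n_perm = 200, seed = 31)
  expect_equal(tab$fraction, planted, tolerance = 0.051)
})

test_that("replicate_rank_correlation matches a rank-then-Pearson oracle", {
  set.seed(71)
  v1 <- rpois(800, 20); v2 <- v1 + rpois(800, 3); v3 <- rev(v1)
  tracks <- list(a = coverage_track(list(c1 = v1), 25),
                 b = coverage_track(list(c1 = v2), 25),
                 c = coverage_track(list(c1 = v3), 25))
  loci <- gr0(rep("c1", 60), seq(0, by = 300, length.out = 60),
              seq(150, by = 300, length.out = 60))
  m <- replicate_rank_correlation(tracks, loci)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  # oracle: mean locus signal, rank, then Pearson
  sig <- vapply(tracks, function(t) {
    vapply(seq_along(loci), function(i) {
      b <- ((GenomicRanges::start(loci)[i] - 1) %/% 25 + 1):
        (ceiling(GenomicRanges::end(loci)[i] / 25))
      mean(t$values$c1[b])
    }, 0)
  }, numeric(60))
  want <- stats::cor(apply(sig, 2, rank))
  expect_equal(unname(m), unname(want), tolerance = 1e-12)
  # identical tracks correlate at exactly 1
  m2 <- replicate_rank_correlation(list(x = tracks$a, y = tracks$a), loci)
  expect_equal(m2["x", "y"], 1)
  # constant signal is reported as missing
  const <- coverage_track(list(c1 = rep(5, 800)), 25)
  m3 <- replicate_rank_correlation(list(a = tracks$a, k = const), loci)
  expect_true(is.na(m3["a", "k"]))
})
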