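---
title: "Deriving and screening Phantom Peak catalogs in ChIP-seq"
author: "phantomPeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and screening Phantom Peak catalogs in ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomPeaks)
```

## The problem

ChIP-seq maps protein--DNA association by antibody enrichment of
crosslinked chromatin.  A class of false positives escapes the usual
quality controls: certain loci -- overwhelmingly the promoters of highly
transcribed genes -- are reproducibly enriched by real antibodies even
when the profiled antigen has been genetically removed.  Such "Phantom
Peaks" pass signal-to-noise and replicate-concordance checks, because the
artifact itself is reproducible.  They are not explained by copy-number
or accessibility biases: they are weak in input chromatin and largely
distinct from high-read-density regions.  The decisive control is an
antigen-null genotype: any peak shared between wild-type chromatin and
chromatin lacking the protein cannot reflect specific
immunoprecipitation.

This package implements that control analysis end to end:

1. derive, per antibody, the peaks shared between wild-type and
   antigen-null profiles (`common_peaks()`);
2. merge the shared sets across antibodies into a phantom catalog with
   per-locus provenance (`build_catalog()`);
3. characterize the catalog -- genomic features, promoter-strength
   dependence, high-read-density-region (HDR) overlap, histone-mark and
   transcription-factor co-occurrence (`feature_distribution()`,
   `expression_quintile_prevalence()`, `derive_hdrs()`,
   `binary_mark_matrix()`, `tf_count_profile()`);
4. screen any external peak set against the catalog with a
   reference-constrained overlap test (`screen_profiles()`), including
   DamID-derived interval sets (`damid_peaks()`, `damid_vs_catalog()`).

A synthetic-data module (`generate_world()` and friends) generates whole
miniature studies with planted ground truth, so every stage is testable
without any sequencing data.

## Interval conventions

All intervals are `GRanges` (1-based, closed), the idiomatic Bioconductor
convention; 0-based half-open formats (BED, bedGraph, the gene-model TSV
dialect, DamID probe positions) are converted at the I/O boundary and
back on write.  Chromosome names are taken verbatim -- no "chr"
stripping or adding -- so a naming mismatch between files surfaces as
zero overlap rather than being silently repaired.  Strand is carried but
ignored by all interval algebra; only gene-model annotation uses it.
The midpoint of an even-width interval is the lower-median base
(`floor((start0 + end0)/2)` in 0-based terms), a deterministic tie-break
used consistently by annotation and consensus calling.

Abutting intervals merge at `min_gap = 0`: "overlapping intervals were
merged" is read as closure under adjacency, and the per-base test
oracles assert the same rule.

## Catalog derivation

`common_peaks(wt, mutant, min_overlap = 50)` marks a wild-type peak as a
false positive when it shares at least 50 bp with some antigen-null
peak.  The *wild-type intervals* (not intersection bases, not mutant
intervals) are reported: Venn-style counts are per-profile peak counts,
and one convention has to be fixed -- WT-anchored is chosen and
documented.  The 50 bp criterion is evaluated per query peak against
each subject peak, never as a summed overlap.

`build_catalog()` merges the union of all common-peak sets base-wise
(order-independently) and records, per merged locus, every contributing
antibody label.  The merged union is the default because partially
overlapping shared regions from different antibodies describe the same
underlying locus.

### Consensus across antibodies

Replicate profiles (different antibodies against the same factor) are
reduced to a consensus list first.  `consensus_peaks()` chains peaks by
single linkage through the >= `min_overlap` relation and emits one
fixed-width peak per group supported by at least `min_support`
replicates, centered on the score-weighted mean of member centers.
Single linkage is order-independent and testable against a brute-force
connected-components oracle; score ties in the greedy stages break by
leftmost coordinate for determinism.

The default `min_support` is *all* replicates -- the conservative
"common peak list" convention.  For the package's reference synthetic
study (three replicates with 10% independent peak dropout) the
end-to-end recovery analyses use `min_support = 2` of 3: requiring all
three replicates retains a true peak with probability $0.9^3 = 0.73$
per genotype, which no downstream step can repair, while 2-of-3 retains
$0.972$ and still suppresses background peaks, which almost never chain
across two independent replicates.

## The fixed-width peak caller

`call_fixed_width_peaks()` is a fully specified, deliberately simple
caller with the one property the analysis depends on: fixed-width peaks
scored against a *local input background*.  Both tracks are first scaled
to a common library size (default $10^6$ reads, the study convention).
Windows of `peak_width` (default 200 bp, a typical sonicated fragment
size) slide at one-bin stride; the expected count is
$\max(\text{local input mean over } \pm 5\,\text{kb},\ \text{genome-wide
input mean})$ scaled to the window width.  A window is a candidate when
the Poisson upper tail $P(X \ge \text{obs})$ falls below
`poisson_alpha` (default $10^{-4}$) *and* obs/expected reaches
`min_fold_over_input` (default 4).  Because normalized counts are not
integers, the tail is evaluated through the gamma identity
$P(\mathrm{Pois}(\lambda) \ge k) = P(\Gamma(k, 1) \le \lambda)$
(`pgamma(lambda, shape = obs)`), which is continuous in the observed
count and agrees with `ppois` at integers.  Candidates are reduced to a
non-overlapping set greedily in decreasing fold order.

Every downstream stage accepts externally produced BED peak sets, so
the caller is bypassable whenever peaks from a dedicated caller are
available.

## High read density regions

`derive_hdrs()` ranks *all* genome bins (zeros included) and selects
those reaching the top-`top_fraction` threshold.  "Top $X$%" selections
here and in the DamID module use the $k$-th largest value with
$k = \max(1, \lfloor fn \rfloor)$ as the threshold, with all ties at the
threshold included -- deterministic and order-independent.  Including
zero bins in the rank is what makes the merged-region genome fraction
exceed the bin fraction, as observed for real input libraries.  An
all-equal track has no definable top set and is rejected
("quantile degenerate") rather than guessed at.

The catalog *retains* HDR-overlapping loci by default and reports the
overlap fraction; `hdr_overlap_fraction(..., filter = TRUE)` returns the
filtered catalog for users who want HDR-clean loci.  The HDR overlap
criterion defaults to 1 bp -- the most conservative flagging -- and is
configurable.

## Annotation

Feature assignment is midpoint-based with the fixed priority
promoter > TTS > exon > intron > intergenic, so category fractions
partition to one (a pie-chart presentation).  "Promoter" means TSS
$\pm$ `promoter_halfwidth` (default 1000 bp; the half-width is a
parameter because "a region of 1000 bp around the TSS" admits both
$\pm 500$ and $\pm 1000$ readings).  The TTS window is analogous.  Ties
between genes break by smaller $|$distance to TSS$|$, then lexicographic
gene id.

`expression_quintile_prevalence()` ranks genes by expression
(unitless; only ranks are used), splits them into five equal groups
(remainder genes to the lower-expression groups), and reports per group
the fraction of promoters containing at least one catalog-locus
midpoint.  Genes without expression values are excluded and tallied.

`binary_mark_matrix()` (0/1 overlap against labeled peak sets, e.g.
histone marks or chromatin states) and `tf_count_profile()` (distinct
transcription factors per locus; loci bound by more than 8 are "HOT"
regions) consume any labeled `GRanges` list -- external segmentations
are just another labeled set, no state-calling is implemented.

## The reference-constrained overlap test

Both phantom loci and most chromatin-factor peak sets concentrate near
active promoters.  Under a genome-wide null, nearly any promoter-bound
profile would overlap the catalog "significantly" -- the test would
measure promoter preference, not catalog affinity.  The screening test
therefore conditions on the shared preference: the reference universe is
the merged union of 4-kb windows centered at every TSS
(`reference_regions()`), and under the null each query peak is
independently relocated, width preserved, to a uniformly random position
that fits entirely inside a single reference region.  Peaks observed
outside the reference are still relocated into it; peaks wider than
every reference region cannot be placed and are excluded and reported.

The statistic $T$ counts query peaks overlapping the catalog by at
least `min_overlap` bp (default 50).  Two p-values are reported:

* `p_perm`: the add-one Monte-Carlo estimator
  $(1 + \#\{T^* \ge T\})/(1 + n_{\text{perm}})$, seed-reproducible.
* `p_analytic`: the exact tail of $T$ under the null.  For each peak
  width $w$, the per-peak success probability $q_w$ is the number of
  allowed start positions yielding a qualifying overlap divided by the
  number of allowed start positions -- both computed exactly as unions
  of integer intervals in an indexed placement space, not sampled.  $T$
  is then Poisson-binomial over the per-peak $q_{w_i}$, evaluated by
  direct convolution; with a uniform-width query this reduces to a
  binomial tail.

The two routes check each other: tests assert that `p_analytic` equals
full enumeration of start positions on small instances and that
`p_perm` agrees within Monte-Carlo error.  Because $T$ is discrete and
the add-one estimator is conservative, the realized type-I rate at
$\alpha = 0.05$ sits slightly below nominal (about 0.040 with 999
permutations on the reference synthetic study); the calibration test
verifies it falls inside the binomial 95% confidence band around 0.05.

`screen_profiles()` runs the test per profile (per-profile failures are
caught, not propagated), adds Benjamini--Hochberg adjusted p-values in a
separate column, and flags profiles with overlap fraction above 20% at
p < 0.05 -- the flagging uses the plain per-profile p-value, with the BH
column available for stricter readings.  The p-value is profile-level
throughout; no per-peak p-values are produced.

`replicate_rank_correlation()` supports replicate QC over the catalog:
mean per-locus track signal, Spearman-correlated pairwise.

## DamID derivation

DamID is antibody-free, so agreement (or not) between a DamID profile
and the catalog separates genuine binding from
immunoprecipitation-stage artifacts.  `damid_peaks()` selects the
top-1% scoring probes (same top-$k$ tie rule), extends each
symmetrically to a total width of 1 kb centered on the probe coordinate
-- probes are point coordinates after remapping, and symmetric extension
is the only strand-free reading -- and merges.  The quantile is computed
per probe table; `damid_vs_catalog()` then delegates to the
reference-constrained test.

## The synthetic study

`synthetic_config()` defines the reference desk-scale study used by the
test suite and the acceptance script.  Defaults, chosen once:

| parameter | default | why |
|---|---|---|
| genome | 1 chromosome, 2 Mb | desk-scale, ~500 gene slots |
| genes | 500, non-overlapping, 1--3 exons | density similar to a gene-rich fly chromosome arm |
| expression | log-normal(meanlog 1, sdlog 1) | right-skewed, rank-based analyses only |
| sticky propensity | plogis(-2 + 2.5 u), u = expression-rank percentile | ~30% of genes sticky, prevalence rising with promoter strength |
| factors x replicates | 2 x 3 | two antibodies with replicate profiles |
| peak width | 200 bp | sonicated fragment scale |
| replicate jitter / dropout | sd 20 bp / 0.1 | realistic center wobble and miss rate |
| background peaks | 5 per Mb per replicate | un-reproducible caller noise |
| coverage | Poisson, 10 reads per 25-bp bin | ~0.8 Mio reads per library |
| HDR loci | 1% of genes, 2-kb windows, 10x input depth | copy-number-like input artifacts |
| DamID probes | every 100 bp, N(0,1) + 4 inside targets | tiling-array scale scores |

Sticky loci sit exactly at TSSs (making promoter fractions analytically
predictable in tests); wild-type profiles contain sticky plus genuine
loci, antigen-null profiles sticky loci only; genuine loci are drawn
uniformly, disjoint from sticky loci.  All randomness flows from one
root seed through per-stage child seeds derived by stable string
hashing, so each stage is independently reproducible and artifacts are
byte-identical across reruns.

The generator's knobs map one-to-one onto the behaviors they exercise:
jitter -> consensus centering, dropout -> `min_support`, propensity
slope -> quintile monotonicity, HDR fraction -> the HDR filter, DamID
shift -> probe-derived interval recovery.

What the generator does *not* emulate: read-level artifacts (duplicate
reads, mappability, fragment-size effects), broad enrichment domains,
correlated replicate failures, or the chromatin-state structure of a
real genome.  Passing tests therefore demonstrate the correctness of
the interval logic, the estimators and the recovery behavior under the
planted statistical structure -- not performance on any particular real
library.

## Numerical choices and degenerate inputs

* Quantile-type selections use the top-$k$ order statistic with ties
  included (see above); all-equal inputs are rejected.
* The permutation null samples placements in an exact integer index
  space; no rejection sampling, no edge effects.
* Empty peak sets screen with an error ("no peaks to screen"); empty
  catalogs and empty mark sets are valid and give zero columns or
  fractions.
* Greedy and tie-prone steps (peak selection, gene assignment,
  expression ranking) all have deterministic tie-breaks, so every
  output is invariant to input ordering.

## Problem sizes

The shipped test suite runs the reference study at 2 Mb / 500 genes,
the interval-kernel oracle suite at 1000 random instances on 10-kb
chromosomes, and the calibration study at 200 peaks x 500 replicates x
999 permutations.  These sizes make the whole suite complete in a few
minutes on one CPU while leaving every statistical check
well-powered; all of them scale up linearly through the same interfaces.

## Limitations

* The screening null treats query peaks as independent; spacing
  constraints among peaks (e.g. minimum inter-peak distances imposed by
  callers) are not preserved.
* The caller is intentionally minimal -- no duplicate handling,
  fragment-size estimation or broad-domain mode -- and is meant to be
  swapped out for a dedicated caller via BED inputs.
* A catalog derived at desk scale from synthetic data characterizes the
  pipeline, not any organism; real catalogs require the corresponding
  full-scale wild-type and antigen-null libraries.
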