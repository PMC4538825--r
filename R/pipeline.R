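## End-to-end orchestration: (optional simulation) -> peak calling ->
## consensus per factor/genotype -> WT/mutant common peaks -> catalog ->
## HDR derivation and overlap -> annotation -> screening -> DamID.
## Configuration is a single YAML file with one section per stage; every
## artifact is written with a provenance header and per-stage record
## counts are logged.

.cfg_get <- function(cfg, path, default = NULL, required = FALSE) {
  node <- cfg
  for (k in path) {
    if (is.null(node[[k]])) {
      if (required)
        stop("config missing required field: ", paste(path, collapse = "."),
             call. = FALSE)
      return(default)
    }
    node <- node[[k]]
  }
  node
}

#' Run the full phantom-peak analysis from a config file
#'
#' The YAML config either contains a `simulate:` block (fields mirroring
#' [synthetic_config()]) or an `inputs:` block naming files per stage
#' (`wt_peaks`/`mutant_peaks` per factor, `input_coverage`, `genes`,
#' `expression`, `damid`).  Stage parameter sections: `consensus`
#' (`min_support`, `min_overlap`), `common` (`min_overlap`), `catalog`
#' (`merge_gap`), `hdr` (`top_fraction`), `annotate`
#' (`promoter_halfwidth`), `screen` (`ref_width`, `min_overlap`,
#' `n_perm`).  Required fields are validated before any stage runs.
#'
#' @param config path to a YAML config file, or an equivalent list.
#' @param outdir output directory (created if missing).
#' @param seed root seed; overrides the config's `seed` field.
#' @return invisibly, a list with `artifacts` (paths), `counts`
#'   (per-stage record counts) and the derived `catalog`.
#' @export
run_full_analysis <- function(config, outdir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("'config' must be a YAML file path or a list")
  seed <- if (!is.null(seed)) as.integer(seed)
          else .cfg_get(cfg, "seed", default = 1L)
  simulate <- !is.null(cfg$simulate)
  if (!simulate && is.null(cfg$inputs))
    stop("config must contain either a 'simulate' or an 'inputs' block")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  prov <- function(stage, ...) {
    sprintf("stage=%s seed=%d %s", stage, seed,
            paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                  collapse = " "))
  }
  counts <- list()
  artifacts <- list()
  log_stage <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))

  min_support <- .cfg_get(cfg, c("consensus", "min_support"))
  consensus_ov <- .cfg_get(cfg, c("consensus", "min_overlap"), 50L)
  common_ov <- .cfg_get(cfg, c("common", "min_overlap"), 50L)
  merge_gap <- .cfg_get(cfg, c("catalog", "merge_gap"), 0L)
  hdr_top <- .cfg_get(cfg, c("hdr", "top_fraction"), 0.01)
  prom_hw <- .cfg_get(cfg, c("annotate", "promoter_halfwidth"), 1000L)
  ref_width <- .cfg_get(cfg, c("screen", "ref_width"), 4000L)
  screen_ov <- .cfg_get(cfg, c("screen", "min_overlap"), 50L)
  n_perm <- .cfg_get(cfg, c("screen", "n_perm"), 1000L)

  if (simulate) {
    sim_args <- cfg$simulate
    sim_args$seed <- seed
    known <- names(formals(synthetic_config))
    bad <- setdiff(names(sim_args), known)
    if (length(bad)) stop("unknown simulate field(s): ",
                          paste(bad, collapse = ", "))
    scfg <- do.call(synthetic_config, sim_args)
    truth <- generate_world(scfg)
    log_stage("simulate", "%d genes, %d sticky loci, %d HDR regions",
              nrow(truth$models$genes), length(truth$sticky_loci),
              length(truth$hdr_loci))
    factors <- scfg$factors
    reps <- list()
    for (f in factors) for (gt in c("WT", "mutant")) {
      sets <- simulate_peak_sets(truth, scfg, genotype = gt, factor = f)
      for (nm in names(sets)) {
        p <- file.path(outdir, paste0(nm, ".bed"))
        write_bed(sets[[nm]], p, prov("simulate", factor = f, genotype = gt))
        artifacts[[nm]] <- p
      }
      reps[[paste(f, gt, sep = "_")]] <- sets
    }
    input_track <- simulate_coverage(truth, scfg, role = "input")
    artifacts$input_coverage <- file.path(outdir, "input.bedgraph")
    write_bedgraph(input_track, artifacts$input_coverage, prov("simulate"))
    models <- truth$models
    expr <- truth$expression
    artifacts$genes <- write_gene_models(models, file.path(outdir, "genes.tsv"))
    artifacts$expression <- write_expression(expr, file.path(outdir, "expr.tsv"))
    damid_tab <- simulate_damid(truth, scfg, target_loci = truth$sticky_loci)
    artifacts$damid <- write_damid(damid_tab, file.path(outdir, "damid.tsv"))
    artifacts$truth_sticky <- file.path(outdir, "truth_sticky.bed")
    write_bed(truth$sticky_loci, artifacts$truth_sticky, prov("simulate"))
  } else {
    inputs <- cfg$inputs
    factors <- names(.cfg_get(cfg, c("inputs", "factors"), required = TRUE))
    reps <- list()
    for (f in factors) {
      for (gt in c("WT", "mutant")) {
        key <- if (gt == "WT") "wt_peaks" else "mutant_peaks"
        paths <- .cfg_get(cfg, c("inputs", "factors", f, key), required = TRUE)
        reps[[paste(f, gt, sep = "_")]] <- lapply(paths, read_bed)
      }
    }
    input_track <- read_bedgraph(
      .cfg_get(cfg, c("inputs", "input_coverage"), required = TRUE))
    models <- read_gene_models(.cfg_get(cfg, c("inputs", "genes"),
                                        required = TRUE))
    expr_path <- .cfg_get(cfg, c("inputs", "expression"))
    expr <- if (!is.null(expr_path)) read_expression(expr_path) else NULL
    damid_path <- .cfg_get(cfg, c("inputs", "damid"))
    damid_tab <- if (!is.null(damid_path)) read_damid(damid_path) else NULL
  }

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  common_sets <- list()
  for (f in factors) {
    cons <- list()
    for (gt in c("WT", "mutant")) {
      rlist <- reps[[paste(f, gt, sep = "_")]]
      ms <- if (is.null(min_support)) length(rlist) else min_support
      cons[[gt]] <- run_stage("consensus", function()
        consensus_peaks(rlist, min_support = ms, min_overlap = consensus_ov))
      p <- file.path(outdir, sprintf("%s_%s_consensus.bed", f, gt))
      write_bed(cons[[gt]], p, prov("consensus", factor = f, genotype = gt,
                                    min_support = ms))
      artifacts[[sprintf("%s_%s_consensus", f, gt)]] <- p
      log_stage("consensus", "%s %s: %d peaks", f, gt, length(cons[[gt]]))
    }
    cm <- run_stage("common", function()
      common_peaks(cons$WT, cons$mutant, min_overlap = common_ov))
    counts[[paste0("common_", f)]] <- attr(cm, "counts")
    log_stage("common", "%s: %d common of %d WT / %d mutant", f, length(cm),
              length(cons$WT), length(cons$mutant))
    p <- file.path(outdir, sprintf("%s_common.bed", f))
    write_bed(cm, p, prov("common", factor = f, min_overlap = common_ov))
    artifacts[[paste0(f, "_common")]] <- p
    common_sets[[f]] <- cm
  }
  catalog <- run_stage("catalog", function()
    build_catalog(common_sets, merge_gap = merge_gap))
  counts$catalog_size <- length(catalog$loci)
  log_stage("catalog", "%d loci", length(catalog$loci))
  artifacts$catalog <- file.path(outdir, "catalog.bed")
  cat_out <- catalog$loci
  S4Vectors::mcols(cat_out)$name <- S4Vectors::mcols(cat_out)$provenance
  S4Vectors::mcols(cat_out)$provenance <- NULL
  write_bed(cat_out, artifacts$catalog, prov("catalog", merge_gap = merge_gap))

  hdrs <- run_stage("hdr", function() derive_hdrs(input_track, hdr_top))
  hov <- hdr_overlap_fraction(catalog, hdrs)
  counts$hdr_regions <- length(hdrs$regions)
  counts$hdr_genome_fraction <- hdrs$genome_fraction
  counts$catalog_hdr_overlap <- hov$fraction
  log_stage("hdr", "%d regions (%.2f%% of genome); %.1f%% of catalog overlaps",
            length(hdrs$regions), 100 * hdrs$genome_fraction,
            100 * hov$fraction)
  artifacts$hdrs <- file.path(outdir, "hdrs.bed")
  write_bed(hdrs$regions, artifacts$hdrs, prov("hdr", top = hdr_top))

  feat <- run_stage("annotate", function()
    feature_distribution(catalog, models, promoter_halfwidth = prom_hw))
  tssf <- tss_window_fraction(catalog, models, window_total = ref_width)
  counts$feature_fractions <- feat
  counts$tss_window_fraction <- tssf
  log_stage("annotate", "promoter %.1f%%, 4kb-TSS-window %.1f%%",
            100 * feat[["promoter"]], 100 * tssf)
  report <- list(feature_fractions = as.list(feat),
                 tss_window_fraction = tssf,
                 catalog_size = length(catalog$loci),
                 hdr_genome_fraction = hdrs$genome_fraction,
                 catalog_hdr_overlap = hov$fraction)
  if (!is.null(expr)) {
    quint <- run_stage("annotate", function()
      expression_quintile_prevalence(models, expr, catalog,
                                     promoter_halfwidth = prom_hw))
    counts$quintile_prevalence <- quint$prevalence
    report$quintile_prevalence <- quint$prevalence
    log_stage("annotate", "quintile prevalence: %s",
              paste(sprintf("%.2f", quint$prevalence), collapse = " "))
  }

  ref <- run_stage("screen", function()
    reference_regions(models, window_total = ref_width))
  screen_tab <- run_stage("screen", function()
    screen_profiles(stats::setNames(common_sets, names(common_sets)),
                    catalog, ref, min_overlap = screen_ov,
                    n_perm = n_perm, seed = seed))
  artifacts$screen <- file.path(outdir, "screen.tsv")
  utils::write.table(screen_tab, artifacts$screen, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("screen", "%d profile(s), %d flagged", nrow(screen_tab),
            attr(screen_tab, "n_flagged"))

  if (!is.null(damid_tab)) {
    dregions <- run_stage("damid", function() damid_peaks(damid_tab))
    drep <- run_stage("damid", function()
      damid_vs_catalog(dregions, catalog, ref, min_overlap = screen_ov,
                       n_perm = n_perm, seed = seed))
    artifacts$damid_peaks <- file.path(outdir, "damid_peaks.bed")
    write_bed(dregions, artifacts$damid_peaks, prov("damid"))
    counts$damid_regions <- length(dregions)
    counts$damid_fraction <- drep$fraction
    report$damid_fraction <- drep$fraction
    log_stage("damid", "%d regions, catalog overlap fraction %.2f (p=%.3g)",
              length(dregions), drep$fraction, drep$p_perm)
  }
  artifacts$report <- file.path(outdir, "report.json")
  jsonlite::write_json(report, artifacts$report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(artifacts = artifacts, counts = counts, catalog = catalog))
}
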