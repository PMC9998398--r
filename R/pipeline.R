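pipeline_defaults <- function() list(
  # paths (NULL = simulate a fixture into outdir/fixture first)
  fixture_dir = NULL,
  outdir = NULL,
  simulate = TRUE,
  # DMR calling (study defaults: 100-bp bins, CG, 5X in all lines,
  # |delta| >= 0.20, p < 0.01, >= 2 methylated reference CpGs)
  bin_width = 100L, context = "CG", min_cov = 5L, min_delta = 0.20,
  max_p = 0.01, min_ref_meth_cpg = 2L,
  # expression thresholds
  lfc_thr = 1, fdr_thr = 0.01,
  # regulatory windows (bp)
  windows = c(0L, 500L, 1000L),
  # simulator overrides (passed to sim_config)
  sim = list(),
  seed = 42L)

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a list; fills defaults, reports every
#' problem at once (not fail-fast) and rejects unknown keys.
#'
#' @param config path to a YAML or JSON file, or a named list.
#' @return a normalized list of class `pipeline_config`; aborts with the
#'   full error list otherwise.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
        simplifyVector = TRUE)
      else yaml::read_yaml(config)
    config <- config %||% list()
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$bin_width) && cfg$bin_width >= 1,
      "bin_width must be >= 1")
  chk(cfg$context %in% c("CG", "CHG", "CHH"),
      "context must be one of CG, CHG, CHH")
  chk(is.numeric(cfg$min_cov) && cfg$min_cov >= 0, "min_cov must be >= 0")
  chk(is.numeric(cfg$min_delta) && cfg$min_delta >= 0 && cfg$min_delta <= 1.01,
      "min_delta must be in [0, 1]")
  chk(is.numeric(cfg$max_p) && cfg$max_p > 0 && cfg$max_p <= 1,
      "max_p must be in (0, 1]")
  chk(is.numeric(cfg$min_ref_meth_cpg) && cfg$min_ref_meth_cpg >= 0,
      "min_ref_meth_cpg must be >= 0")
  chk(is.numeric(cfg$lfc_thr) && cfg$lfc_thr > 0, "lfc_thr must be > 0")
  chk(is.numeric(cfg$fdr_thr) && cfg$fdr_thr > 0 && cfg$fdr_thr <= 1,
      "fdr_thr must be in (0, 1]")
  chk(is.numeric(cfg$windows) && all(cfg$windows >= 0),
      "windows must be >= 0")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed must be a single integer")
  if (!is.null(cfg$fixture_dir)) {
    cfg$simulate <- FALSE
    if (!dir.exists(cfg$fixture_dir))
      errors <- c(errors, sprintf("fixture_dir does not exist: %s",
                                  cfg$fixture_dir))
  }
  if (length(errors))
    stopf("invalid configuration:\n%s",
          paste0("  - ", errors, collapse = "\n"))
  cfg$seed <- as.integer(cfg$seed)
  cfg$windows <- sort(unique(as.integer(cfg$windows)))
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) digest::digest(unclass(cfg), algo = "sha256")

#' Run the full methylome analysis pipeline
#'
#' Orchestrates: fixture simulation (or loading), context assignment, the
#' study-wide coverage filter, per-feature methylation matrices, DMR calling
#' for each knockout against the reference, consensus hypoDMRs, annotation
#' and histone-mark overlap, and expression integration. Writes DMR BEDs,
#' methylation matrices, category tables and a JSON report; the report
#' carries the config (with its hash) in its header so every threshold
#' choice is traceable. Deterministic given config and seed.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param outdir output directory (overrides `config$outdir`).
#' @return the report, a list of class `run_report`, invisibly; written to
#'   `outdir/report.json`.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  outdir <- outdir %||% cfg$outdir
  if (is.null(outdir)) stopf("an output directory is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  fxdir <- stage("simulate", {
    if (cfg$simulate) {
      fx <- file.path(outdir, "fixture")
      scfg <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                    as.list(cfg$sim)))
      write_fixture_set(fx, scfg, force = TRUE)
      fx
    } else cfg$fixture_dir
  })

  inputs <- stage("load", load_fixture(fxdir))
  lens <- chrom_lengths(inputs$genome)
  samples <- inputs$samples
  ref <- samples[[1]]; kos <- samples[-1]

  positions <- stage("coverage_filter",
    filter_by_coverage(samples, cfg$min_cov, cfg$context))

  mat <- stage("methylation", {
    feats <- c(inputs$annotations$tes, inputs$annotations$genes)
    m <- feature_methylation_matrix(samples, feats, cfg$context, positions)
    utils::write.csv(m, file.path(outdir, "feature_methylation.csv"))
    m
  })

  dmr_sets <- stage("dmr", {
    out <- lapply(kos, function(ko)
      call_dmrs(ref, ko, lens, positions, bin_width = cfg$bin_width,
                context = cfg$context, min_cov = cfg$min_cov,
                min_delta = cfg$min_delta, max_p = cfg$max_p,
                min_ref_meth_cpg = cfg$min_ref_meth_cpg))
    names(out) <- vapply(kos, `[[`, "", "sample_id")
    for (nm in names(out))
      write_bed(out[[nm]], file.path(outdir, sprintf("dmrs_%s.bed", nm)))
    out
  })

  cons <- stage("consensus", {
    cs <- consensus_dmrs(dmr_sets[[1]], dmr_sets[[2]], "hypo")
    write_bed(cs$common, file.path(outdir, "common_hypodmrs.bed"))
    cs
  })

  ov <- stage("overlap", {
    res <- list()
    for (cls in c("genes", "tes", "te_genes")) {
      feats <- inputs$annotations[[cls]]
      res[[cls]] <- lapply(stats::setNames(nm = cfg$windows), function(w)
        windowed_overlap(feats, cons$common, w, lens)[c("n_hit", "percent")])
    }
    res$histone <- histone_membership(cons$common, inputs$peaks)
    res
  })

  integ <- stage("integrate", {
    classif <- classify_expression(inputs$de_tables, cfg$lfc_thr, cfg$fdr_thr)
    link <- link_dmr_expression(classif, cons$common,
                                inputs$annotations$te_genes,
                                cfg$windows, lens)
    zs <- lapply(inputs$de_tables, function(tb) {
      teg <- intersect(tb$feature_id, mcols(inputs$annotations$te_genes)$name)
      up <- intersect(unlist(classif$sets[grep("^up", names(classif$sets))]),
                      teg)
      if (length(up) >= 2) lfc_zscore(tb, up) else NULL
    })
    up_te <- inputs$annotations$te_genes[
      mcols(inputs$annotations$te_genes)$name %in% classif$sets$up_both]
    lens_cmp <- compare_te_lengths(up_te, cons$common)
    fwrite(classif$table, file.path(outdir, "expression_categories.tsv"),
           sep = "\t")
    fwrite(link$percent, file.path(outdir, "category_window_overlap.tsv"),
           sep = "\t")
    list(classif = classif, link = link, zscores = zs, lengths = lens_cmp)
  })

  recovery <- if (!is.null(inputs$truth))
    stage("recovery", truth_recovery(inputs$truth, dmr_sets, cons, lens,
                                     cfg)) else NULL

  report <- list(
    tool = "dmrcall", version = as.character(utils::packageVersion("dmrcall")),
    config = unclass(cfg), config_hash = config_hash(cfg),
    n_cytosines_retained = nrow(positions),
    samples = vapply(samples, `[[`, "", "sample_id"),
    dmr_counts = lapply(dmr_sets, function(g) list(
      total = length(g),
      hypo = sum(mcols(g)$direction == "hypo"),
      hyper = sum(mcols(g)$direction == "hyper"),
      n_testable_bins = metadata(g)$n_testable,
      n_skipped_bins = metadata(g)$n_skipped)),
    consensus = cons[c("shared_a", "shared_b", "n_a", "n_b", "n_common")],
    genome_fraction_pct = genome_fraction(cons$common, lens),
    annotation_overlap = ov[c("genes", "tes", "te_genes")],
    histone_combination_counts = as.list(ov$histone$combination_counts),
    histone_marginals = as.list(ov$histone$marginals),
    expression_set_sizes = lapply(integ$classif$sets, length),
    category_window_overlap = integ$link$percent,
    regulatory_attributions = integ$link$regulatory,
    te_length_wilcoxon = if (!is.null(integ$lengths$test))
      integ$lengths$test[c("statistic", "p", "method")] else NULL,
    truth_recovery = recovery)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "columns")
  message(sprintf("pipeline finished: %d/%d hypoDMRs (%s/%s), %d common",
                  cons$n_a, cons$n_b, names(dmr_sets)[1], names(dmr_sets)[2],
                  cons$n_common))
  invisible(structure(report, class = "run_report"))
}

# Load a fixture directory written by write_fixture_set() (or assembled by
# hand in the same layout).
load_fixture <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  lens <- chrom_lengths(genome)
  reports <- dir(dir, pattern = "\\.cytosine_report\\.tsv$")
  if (!length(reports)) stopf("no cytosine reports in %s", dir)
  sids <- sub("\\.cytosine_report\\.tsv$", "", reports)
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    want <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)$sample_ids
    if (!is.null(want) && all(want %in% sids)) sids <- want
  }
  samples <- lapply(sids, function(sid)
    read_cytosine_report(file.path(dir, paste0(sid, ".cytosine_report.tsv")),
                         sid))
  ann <- list(
    genes = read_bed_annotations(file.path(dir, "genes.bed"), "gene", lens),
    tes = read_bed_annotations(file.path(dir, "tes.bed"), "TE", lens),
    te_genes = read_bed_annotations(file.path(dir, "te_genes.bed"),
                                    "TE_gene", lens))
  pk_files <- dir(dir, pattern = "^peaks_.*\\.bed$")
  peaks <- lapply(pk_files, function(f)
    read_bed_annotations(file.path(dir, f), "peak", lens))
  names(peaks) <- sub("^peaks_(.*)\\.bed$", "\\1", pk_files)
  de_files <- dir(dir, pattern = "^de_.*\\.tsv$")
  de <- lapply(de_files, function(f)
    read_de_table(file.path(dir, f), sub("^de_(.*)\\.tsv$", "\\1", f)))
  names(de) <- sub("^de_(.*)\\.tsv$", "\\1", de_files)
  truth <- if (file.exists(file.path(dir, "truth.json")))
    read_truth_json(file.path(dir, "truth.json")) else NULL
  list(genome = genome, samples = samples, annotations = ann, peaks = peaks,
       de_tables = de, truth = truth)
}

# Planted-truth recovery metrics: fraction of well-covered island bins
# recalled as hypoDMRs per knockout, and consensus sharing.
truth_recovery <- function(truth, dmr_sets, cons, lens, cfg,
                           min_cpg_per_bin = 5L) {
  rec <- lapply(dmr_sets, function(set) {
    island_bin_recall(set, truth$island_intervals, lens, cfg,
                      min_cpg_per_bin)
  })
  list(island_bin_recall = rec,
       consensus_shared_min = min(cons$shared_a, cons$shared_b))
}

#' Fraction of planted island bins recalled as hypoDMRs
#'
#' Considers the grid bins lying fully inside planted islands that were
#' testable with at least `min_cpg_per_bin` retained cytosines, and reports
#' the fraction called hypoDMRs.
#'
#' @param dmr_set DMR `GRanges` from [call_dmrs()] (its metadata supplies
#'   the grid and thresholds used).
#' @param islands planted island `GRanges`.
#' @param chrom_lengths named lengths.
#' @param cfg pipeline or DMR parameter list with `bin_width`.
#' @param min_cpg_per_bin minimum retained cytosines for a bin to count
#'   toward the denominator.
#' @param bin_stats optional precomputed [aggregate_counts()] table; when
#'   absent the denominator falls back to all island-interior bins.
#' @return list with `n_island_bins`, `n_recalled`, `recall`.
#' @export
island_bin_recall <- function(dmr_set, islands, chrom_lengths, cfg,
                              min_cpg_per_bin = 5L, bin_stats = NULL) {
  bw <- metadata(dmr_set)$params$bin_width %||% cfg$bin_width
  bins <- make_bins(chrom_lengths, bw)
  inside <- IRanges::overlapsAny(bins, islands, type = "within",
                                       ignore.strand = TRUE)
  cand <- bins[inside]
  if (!is.null(bin_stats)) {
    key <- paste0(bin_stats$chrom, ":", bin_stats$start, recycle0 = TRUE)
    ck <- paste0(as.character(GenomeInfoDb::seqnames(cand)), ":",
                 recycle0 = TRUE,
                 GenomicRanges::start(cand) - 1L)
    idx <- match(ck, key)
    keep <- !is.na(idx) & bin_stats$n_cytosines[idx] >= min_cpg_per_bin &
      bin_stats$n_ref[idx] > 0 & bin_stats$n_treat[idx] > 0
    cand <- cand[keep]
  }
  hypo <- dmr_set[mcols(dmr_set)$direction == "hypo"]
  hit <- IRanges::overlapsAny(cand, hypo, type = "equal",
                                    ignore.strand = TRUE)
  list(n_island_bins = length(cand), n_recalled = sum(hit),
       recall = if (length(cand)) mean(hit) else NA_real_)
}
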