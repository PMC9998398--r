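#' Configuration of the synthetic methylome study
#'
#' Defines a desk-scale emulation of a WGBS study of a genome whose CG
#' methylation is confined to transposable-element islands: a reference line
#' plus two knockout lines in which island methylation is depleted by a
#' constant factor, sequenced at finite coverage, with histone-mark peak
#' sets co-marking the islands and expression tables in which a subset of
#' methylated TEs is planted as upregulated.
#'
#' Defaults encode the study conditions: 80% CG methylation inside islands
#' against a ~2% background, a 4.5-fold knockout depletion (the middle of
#' the observed 4-5-fold loss), 30X mean coverage, and two 500-kb
#' chromosomes carrying 20 islands of 2-5 kb.
#'
#' @param genome_length_per_chrom chromosome length in bp.
#' @param n_chromosomes number of chromosomes.
#' @param gc_content genomic GC fraction in `[0, 1]`.
#' @param te_island_count number of methylated TE islands.
#' @param te_island_length_range island length range in bp (min, max).
#' @param decoy_te_count unmethylated decoy TEs (so that overlap statistics
#'   are non-trivial).
#' @param decoy_te_length_range decoy length range in bp.
#' @param island_cg_methylation true CG methylation level inside islands.
#' @param background_cg_methylation CG level outside islands.
#' @param noncg_methylation constant CHG/CHH level everywhere (non-CG
#'   methylation is scarce in this system).
#' @param ko_depletion_factor factor by which island methylation is divided
#'   in the knockouts.
#' @param mean_coverage Poisson mean of per-cytosine read coverage.
#' @param planted_upregulated_fraction fraction of island (methylated)
#'   TE-genes planted as upregulated in both mutants.
#' @param decoy_upregulated_fraction fraction of decoy (unmethylated)
#'   TE-genes planted as upregulated (methylation-independent derepression).
#' @param planted_lfc_mean,planted_lfc_sd log2 units of the planted effect.
#' @param lfc_noise_sd per-mutant Gaussian noise added to observed LFC.
#' @param fdr_threshold significance boundary used when simulating adjusted
#'   p-values: planted features draw below it, others above.
#' @param gene_length_range gene length range in bp.
#' @param intergenic_gap minimum gap between tiled genes (bp).
#' @param te_families family labels assigned to TEs.
#' @param peak_marks histone-mark labels (three peak sets).
#' @param peak_island_fraction per-mark fraction of islands covered by peaks.
#' @param peak_flank bp by which peaks extend beyond their island.
#' @param sample_ids labels of the reference and the two knockouts.
#' @param seed master seed; fully determines every output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length_per_chrom = 500000L,
                       n_chromosomes = 2L,
                       gc_content = 0.5,
                       te_island_count = 20L,
                       te_island_length_range = c(2000L, 5000L),
                       decoy_te_count = 20L,
                       decoy_te_length_range = c(200L, 500L),
                       island_cg_methylation = 0.80,
                       background_cg_methylation = 0.02,
                       noncg_methylation = 0.005,
                       ko_depletion_factor = 4.5,
                       mean_coverage = 30,
                       planted_upregulated_fraction = 0.5,
                       decoy_upregulated_fraction = 0.3,
                       planted_lfc_mean = 3,
                       planted_lfc_sd = 0.5,
                       lfc_noise_sd = 0.25,
                       fdr_threshold = 0.01,
                       gene_length_range = c(1000L, 2000L),
                       intergenic_gap = 1000L,
                       te_families = c("LTR-copia", "CoDi5", "Gypsy",
                                       "LINE", "PiggyBac", "hAT"),
                       peak_marks = c("H3K27me3", "H3K9me2", "H3K9me3"),
                       peak_island_fraction = c(0.70, 0.85, 0.95),
                       peak_flank = 300L,
                       sample_ids = c("WT", "KO1", "KO2"),
                       seed = 42L) {
  cfg <- as.list(environment())
  frac <- c("gc_content", "island_cg_methylation", "background_cg_methylation",
            "noncg_methylation", "planted_upregulated_fraction",
            "decoy_upregulated_fraction", "fdr_threshold")
  for (f in frac)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("%s must be in [0, 1]", f)
  if (any(cfg$peak_island_fraction < 0 | cfg$peak_island_fraction > 1))
    stopf("peak_island_fraction must be in [0, 1]")
  if (length(cfg$peak_island_fraction) != length(cfg$peak_marks))
    stopf("peak_island_fraction must match peak_marks in length")
  if (cfg$ko_depletion_factor <= 0) stopf("ko_depletion_factor must be > 0")
  if (cfg$mean_coverage < 0) stopf("mean_coverage must be >= 0")
  for (rg in c("te_island_length_range", "decoy_te_length_range",
               "gene_length_range")) {
    v <- cfg[[rg]]
    if (length(v) != 2L || v[1] > v[2] || v[1] < 1)
      stopf("%s must be an increasing positive pair", rg)
  }
  if (cfg$te_island_length_range[2] > cfg$genome_length_per_chrom)
    stopf("islands do not fit inside chromosomes")
  if (length(cfg$sample_ids) != 3L || anyDuplicated(cfg$sample_ids))
    stopf("sample_ids must be 3 distinct labels (reference, KO, KO)")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

# Place `n` non-overlapping intervals of lengths in `len_range` on the given
# chromosomes by rejection sampling; `avoid` is an optional GRanges of
# forbidden space. Bounded retries so impossible configurations fail loudly.
place_intervals <- function(chrom_lengths, n, len_range, avoid = NULL,
                            min_gap = 200L, max_retries = 1000L) {
  placed <- GRanges(seqlengths = chrom_lengths)
  if (n == 0) return(placed)
  chroms <- names(chrom_lengths)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      len <- sample(seq(len_range[1], len_range[2]), 1L)
      chrom <- sample(chroms, 1L, prob = chrom_lengths / sum(chrom_lengths))
      lim <- chrom_lengths[[chrom]] - len
      if (lim < 1) next
      st <- sample.int(lim, 1L)
      cand <- GRanges(chrom, IRanges(st, st + len - 1L),
                      seqlengths = chrom_lengths)
      buf <- GenomicRanges::trim(suppressWarnings(cand + min_gap))
      clash <- IRanges::overlapsAny(buf, placed) ||
        (!is.null(avoid) && IRanges::overlapsAny(buf, avoid))
      if (!clash) { placed <- c(placed, cand); ok <- TRUE; break }
    }
    if (!ok) stopf("could not place interval %d without overlap after %d retries",
                   i, max_retries)
  }
  sort(placed)
}

#' Generate a synthetic genome, annotations and planted methylation truth
#'
#' Draws random chromosome sequences at the configured GC content, places
#' non-overlapping methylated TE islands and unmethylated decoy TEs, tiles
#' the remaining space with genes separated by >= `intergenic_gap`, derives
#' a TE-gene (open-reading-frame) annotation inside every TE, and builds
#' three histone-mark peak sets covering configured subsets of the islands.
#' The returned truth records the planted island levels per sample and, for
#' expression, which TE-genes are upregulated and by how much.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `annotations` (list of
#'   `GRanges`: genes, tes, te_genes), `peaks` (named list of `GRanges`),
#'   `truth` (class `sim_truth`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "genome"), {
    lens <- stats::setNames(rep(config$genome_length_per_chrom,
                                config$n_chromosomes),
                            paste0("chr", seq_len(config$n_chromosomes)))
    p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
           G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
    genome <- Biostrings::DNAStringSet(vapply(lens, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      character(1)))
    islands <- place_intervals(lens, config$te_island_count,
                               config$te_island_length_range)
    decoys <- place_intervals(lens, config$decoy_te_count,
                              config$decoy_te_length_range, avoid = islands)
    tes <- c(islands, decoys)
    if (length(tes)) {
      mcols(tes)$name <- c(sprintf("TE_island_%02d", seq_along(islands)),
                           sprintf("TE_decoy_%02d", seq_along(decoys)))[
                             seq_along(tes)]
      mcols(tes)$family <- sample(config$te_families, length(tes),
                                  replace = TRUE)
      mcols(tes)$feature_class <- "TE"
      mcols(tes)$is_island <- c(rep(TRUE, length(islands)),
                                rep(FALSE, length(decoys)))
      tes <- sort(tes)
    } else {
      mcols(tes) <- S4Vectors::DataFrame(name = character(),
                                         family = character(),
                                         feature_class = character(),
                                         is_island = logical())
    }
    # TE-gene = ORF-like interior of each TE (central 80%, >= 50 bp)
    te_genes <- tes
    if (length(tes)) {
      trim <- pmax(0L, pmin(as.integer(GenomicRanges::width(tes) * 0.1),
                            (GenomicRanges::width(tes) - 50L) %/% 2L))
      te_genes <- GenomicRanges::narrow(tes, start = 1L + trim,
                                        end = GenomicRanges::width(tes) - trim)
      mcols(te_genes)$name <- sub("^TE_", "TEG_", mcols(tes)$name)
      mcols(te_genes)$feature_class <- "TE_gene"
    }
    genes <- tile_genes(lens, tes, config)
    peaks <- make_peak_sets(islands, config, lens)
    truth <- build_truth(tes, te_genes, genes, config)
    list(genome = genome,
         annotations = list(genes = genes, tes = tes, te_genes = te_genes),
         peaks = peaks, truth = truth)
  })
}

tile_genes <- function(lens, tes, config) {
  gaps <- GenomicRanges::gaps(GenomicRanges::reduce(tes))
  gaps <- gaps[GenomicRanges::strand(gaps) == "*"]
  if (!length(tes))
    gaps <- GRanges(names(lens), IRanges(1L, unname(lens)), seqlengths = lens)
  out <- list(); k <- 0L
  for (i in seq_along(gaps)) {
    g <- gaps[i]
    pos <- GenomicRanges::start(g) + config$intergenic_gap
    while (pos + config$gene_length_range[1] - 1L <= GenomicRanges::end(g) -
           config$intergenic_gap) {
      len <- sample(seq(config$gene_length_range[1],
                        config$gene_length_range[2]), 1L)
      en <- min(pos + len - 1L,
                GenomicRanges::end(g) - config$intergenic_gap)
      if (en - pos + 1L < config$gene_length_range[1]) break
      k <- k + 1L
      out[[k]] <- GRanges(GenomeInfoDb::seqnames(g), IRanges(pos, en),
                          seqlengths = lens)
      pos <- en + 1L + config$intergenic_gap
    }
  }
  genes <- if (k) sort(do.call(c, out)) else GRanges(seqlengths = lens)
  mcols(genes)$name <- sprintf("gene_%04d", seq_along(genes))
  mcols(genes)$feature_class <- "gene"
  genes
}

make_peak_sets <- function(islands, config, lens) {
  out <- list()
  for (j in seq_along(config$peak_marks)) {
    n_cov <- round(config$peak_island_fraction[j] * length(islands))
    idx <- if (length(islands)) sort(sample(seq_along(islands), n_cov))
           else integer()
    pk <- islands[idx]
    if (length(pk))
      pk <- GenomicRanges::trim(suppressWarnings(pk + config$peak_flank))
    mcols(pk) <- NULL
    mcols(pk)$name <- sprintf("%s_peak_%02d", config$peak_marks[j],
                              seq_along(pk))
    mcols(pk)$feature_class <- rep("peak", length(pk))
    out[[config$peak_marks[j]]] <- pk
  }
  out
}

build_truth <- function(tes, te_genes, genes, config) {
  is_island <- mcols(tes)$is_island %||% logical(0)
  islands <- tes[is_island]
  mcols(islands) <- S4Vectors::DataFrame(
    name = mcols(tes)$name[is_island], family = mcols(tes)$family[is_island],
    feature_class = rep("TE", sum(is_island)))
  lvl_wt <- rep(config$island_cg_methylation, length(islands))
  lvl_ko <- lvl_wt / config$ko_depletion_factor
  levels <- matrix(c(lvl_wt, lvl_ko, lvl_ko), ncol = 3,
                   dimnames = list(mcols(islands)$name, config$sample_ids))
  island_teg <- sub("^TE_", "TEG_", mcols(islands)$name)
  decoy_teg <- sub("^TE_", "TEG_", mcols(tes)$name[!is_island])
  n_up <- round(config$planted_upregulated_fraction * length(island_teg))
  n_dec <- round(config$decoy_upregulated_fraction * length(decoy_teg))
  up_island <- if (n_up) sort(sample(island_teg, n_up)) else character()
  up_decoy <- if (n_dec) sort(sample(decoy_teg, n_dec)) else character()
  up <- c(up_island, up_decoy)
  true_lfc <- stats::setNames(rep(0, length(te_genes) + length(genes)),
                              c(mcols(te_genes)$name, mcols(genes)$name))
  true_lfc[up] <- stats::rnorm(length(up), config$planted_lfc_mean,
                               config$planted_lfc_sd)
  structure(list(island_intervals = islands, levels = levels,
                 upregulated_te_ids = up, upregulated_island_te_ids = up_island,
                 upregulated_decoy_te_ids = up_decoy, true_lfc = true_lfc),
            class = "sim_truth")
}

#' Simulate a per-cytosine bisulfite report for one sample
#'
#' Every cytosine of the genome (both strands) receives a context from the
#' reference sequence, a coverage drawn from Poisson(`mean_coverage`) and a
#' methylated count drawn from Binomial(coverage, p) where p is the planted
#' island level of the sample inside islands, the CG background outside, and
#' the (small) non-CG level for CHG/CHH sites. Zero-coverage sites are
#' emitted with 0/0 counts, not dropped - downstream coverage filters must
#' handle them. Each sample draws from its own seeded stream.
#'
#' @param genome `DNAStringSet`.
#' @param truth `sim_truth` from [generate_genome()].
#' @param sample_label label of this replicate (also the stream label).
#' @param config a [sim_config()].
#' @param levels_as which column of the truth's level matrix to use; defaults
#'   to `sample_label`, letting e.g. a second WT replicate be drawn with
#'   `sample_label = "WT_rep2", levels_as = "WT"`.
#' @param contexts optional precomputed [assign_contexts()] table.
#' @return a [methylome].
#' @export
simulate_methylome <- function(genome, truth, sample_label, config,
                               levels_as = sample_label, contexts = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  if (!levels_as %in% colnames(truth$levels))
    stopf("unknown sample label '%s' (truth has: %s)", levels_as,
          paste(colnames(truth$levels), collapse = ", "))
  ctx <- contexts %||% assign_contexts(genome)
  dt <- copy(ctx)
  p <- ifelse(dt$context == "CG", config$background_cg_methylation,
              config$noncg_methylation)
  isl <- truth$island_intervals
  if (length(isl)) {
    idt <- data.table(chrom = as.character(GenomeInfoDb::seqnames(isl)),
                      start = GenomicRanges::start(isl),
                      end = GenomicRanges::end(isl),
                      lvl = unname(truth$levels[, levels_as]))
    setkeyv(idt, c("chrom", "start", "end"))
    site <- dt[, list(chrom, start = pos, end = pos)]
    setkeyv(site, c("chrom", "start", "end"))
    hit <- foverlaps(site, idt, type = "within", nomatch = NA, which = TRUE)
    setorder(hit, xid) # islands are disjoint: exactly one row per site
    in_isl <- !is.na(hit$yid) & dt$context == "CG"
    p[in_isl] <- idt$lvl[hit$yid[in_isl]]
  }
  sim <- with_seed(child_seed(config$seed, paste0("methylome:", sample_label)), {
    cv <- stats::rpois(nrow(dt), config$mean_coverage)
    list(cov = cv, m = stats::rbinom(nrow(dt), cv, p))
  })
  data.table::set(dt, j = "m", value = sim$m)
  data.table::set(dt, j = "u", value = sim$cov - sim$m)
  methylome(dt[, list(chrom, pos, strand, m, u, context, tri)], sample_label)
}

#' Simulate per-mutant differential-expression tables
#'
#' Each annotated feature (TE-genes and genes) receives, per mutant, an
#' observed LFC equal to its planted true LFC plus Gaussian noise, and an
#' adjusted p-value drawn below the significance boundary for planted
#' features and uniformly above it otherwise. Both mutants share the planted
#' direction (correlated effects), differing only in noise.
#'
#' @param annotations annotation list from [generate_genome()].
#' @param truth `sim_truth`.
#' @param config a [sim_config()].
#' @return named list of two data.tables (one per KO sample id) with columns
#'   `feature_id`, `log2FoldChange`, `padj`.
#' @export
simulate_expression <- function(annotations, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  ids <- names(truth$true_lfc)
  planted <- truth$true_lfc != 0
  kos <- config$sample_ids[2:3]
  out <- list()
  for (ko in kos) {
    with_seed(child_seed(config$seed, paste0("expression:", ko)), {
      lfc <- truth$true_lfc + stats::rnorm(length(ids), 0, config$lfc_noise_sd)
      fdr <- ifelse(planted,
                    stats::runif(length(ids), 0, config$fdr_threshold / 10),
                    stats::runif(length(ids), config$fdr_threshold, 1))
    })
    out[[ko]] <- data.table(feature_id = ids, log2FoldChange = lfc,
                            padj = fdr)
  }
  out
}

#' Serialize planted truth to JSON (lossless round-trip)
#' @param truth `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  isl <- truth$island_intervals
  obj <- list(
    islands = data.frame(chrom = as.character(GenomeInfoDb::seqnames(isl)),
                         start = GenomicRanges::start(isl) - 1L,
                         end = GenomicRanges::end(isl),
                         name = mcols(isl)$name,
                         family = mcols(isl)$family),
    chrom_lengths = as.list(GenomeInfoDb::seqlengths(isl)),
    levels = as.data.frame(truth$levels),
    level_samples = colnames(truth$levels),
    upregulated_te_ids = truth$upregulated_te_ids,
    upregulated_island_te_ids = truth$upregulated_island_te_ids,
    upregulated_decoy_te_ids = truth$upregulated_decoy_te_ids,
    true_lfc = as.list(truth$true_lfc))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read planted truth back from JSON
#' @param path JSON path written by [write_truth_json()].
#' @return a `sim_truth`.
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lens <- unlist(obj$chrom_lengths)
  isl <- GRanges(obj$islands$chrom,
                 IRanges(obj$islands$start + 1L, obj$islands$end),
                 seqlengths = lens)
  mcols(isl)$name <- obj$islands$name
  mcols(isl)$family <- obj$islands$family
  mcols(isl)$feature_class <- "TE"
  levels <- as.matrix(obj$levels)
  dimnames(levels) <- list(obj$islands$name, obj$level_samples)
  structure(list(island_intervals = isl, levels = levels,
                 upregulated_te_ids = as.character(obj$upregulated_te_ids),
                 upregulated_island_te_ids =
                   as.character(obj$upregulated_island_te_ids),
                 upregulated_decoy_te_ids =
                   as.character(obj$upregulated_decoy_te_ids),
                 true_lfc = unlist(obj$true_lfc)),
            class = "sim_truth")
}

#' Write the complete fixture set to a directory
#'
#' Generates the genome, annotations, three cytosine reports (reference and
#' two knockouts), three histone peak BEDs, two differential-expression
#' tables, the truth JSON and a sha256 manifest. Refuses to write into a
#' non-empty directory unless `force = TRUE`.
#'
#' @param outdir output directory.
#' @param config a [sim_config()].
#' @param force overwrite a non-empty directory.
#' @return data.table manifest (`file`, `sha256`), invisibly; also written
#'   as `manifest.tsv`.
#' @export
write_fixture_set <- function(outdir, config, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stopf("directory '%s' is not empty (use force = TRUE)", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(config)
  Biostrings::writeXStringSet(gen$genome, file.path(outdir, "genome.fa"))
  write_bed(gen$annotations$genes, file.path(outdir, "genes.bed"))
  write_bed(gen$annotations$tes, file.path(outdir, "tes.bed"))
  write_bed(gen$annotations$te_genes, file.path(outdir, "te_genes.bed"))
  for (mk in names(gen$peaks))
    write_bed(gen$peaks[[mk]], file.path(outdir, sprintf("peaks_%s.bed", mk)))
  ctx <- assign_contexts(gen$genome)
  for (sid in config$sample_ids) {
    s <- simulate_methylome(gen$genome, gen$truth, sid, config,
                            contexts = ctx)
    write_cytosine_report(s, file.path(outdir, sprintf("%s.cytosine_report.tsv",
                                                       sid)))
  }
  de <- simulate_expression(gen$annotations, gen$truth, config)
  for (ko in names(de))
    fwrite(de[[ko]], file.path(outdir, sprintf("de_%s.tsv", ko)), sep = "\t")
  write_truth_json(gen$truth, file.path(outdir, "truth.json"))
  jsonlite::write_json(unclass(config), file.path(outdir, "config.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  files <- sort(setdiff(dir(outdir), "manifest.tsv"))
  manifest <- data.table(file = files,
                         sha256 = file_sha256(file.path(outdir, files)))
  fwrite(manifest, file.path(outdir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}
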