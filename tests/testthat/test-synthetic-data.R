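test_that("generated genome and annotations echo the configuration", {
  cfg <- sim_config(genome_length_per_chrom = 50000L, n_chromosomes = 2L,
                    te_island_count = 4L,
                    te_island_length_range = c(800L, 1500L),
                    decoy_te_count = 3L, seed = 3L)
  gen <- generate_genome(cfg)
  expect_length(gen$genome, 2L)
  expect_true(all(Biostrings::width(gen$genome) == 50000L))
  tes <- gen$annotations$tes
  expect_equal(sum(S4Vectors::mcols(tes)$is_island), 4L)
  expect_equal(length(tes), 7L)
  expect_length(gen$truth$island_intervals, 4L)
  # islands are disjoint and every planted island is a TE annotation
  expect_equal(length(GenomicRanges::reduce(gen$truth$island_intervals)), 4L)
  expect_true(all(IRanges::overlapsAny(gen$truth$island_intervals, tes,
                                       type = "equal")))
  # TE-genes nest inside their TEs; genes keep clear of TEs
  expect_true(all(IRanges::overlapsAny(gen$annotations$te_genes, tes,
                                       type = "within")))
  expect_false(any(IRanges::overlapsAny(gen$annotations$genes, tes)))
  expect_length(gen$peaks, 3L)
})

test_that("island-free configuration yields gene-only annotations", {
  cfg <- sim_config(genome_length_per_chrom = 30000L, n_chromosomes = 1L,
                    te_island_count = 0L, decoy_te_count = 0L,
                    planted_upregulated_fraction = 0,
                    decoy_upregulated_fraction = 0, seed = 9L)
  gen <- generate_genome(cfg)
  expect_length(gen$annotations$tes, 0L)
  expect_gt(length(gen$annotations$genes), 0L)
  expect_length(gen$truth$island_intervals, 0L)
})

test_that("impossible island placement fails with a placement error", {
  cfg <- sim_config(genome_length_per_chrom = 10000L, n_chromosomes = 1L,
                    te_island_count = 10L,
                    te_island_length_range = c(4000L, 5000L), seed = 2L)
  expect_error(generate_genome(cfg), "could not place")
})

test_that("a fixed seed reproduces the fixture set byte for byte", {
  cfg <- small_sim_config(seed = 77L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_fixture_set(d1, cfg, force = TRUE)
  m2 <- write_fixture_set(d2, cfg, force = TRUE)
  expect_equal(m1$file, m2$file)
  expect_equal(m1$sha256, m2$sha256)
  expect_gte(nrow(m1), 10L)
  # refuses to clobber a non-empty directory
  expect_error(write_fixture_set(d1, cfg), "not empty")
})

test_that("fixture files round-trip through their module readers", {
  cfg <- small_sim_config(seed = 55L)
  d <- withr::local_tempdir()
  write_fixture_set(d, cfg, force = TRUE)
  genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  wt <- read_cytosine_report(file.path(d, "WT.cytosine_report.tsv"))
  expect_s3_class(wt, "methylome")
  expect_gt(nrow(wt$records), 0L)
  tes <- read_bed_annotations(file.path(d, "tes.bed"), "TE", lens)
  expect_true(all(!is.na(S4Vectors::mcols(tes)$family)))
  de <- read_de_table(file.path(d, "de_KO1.tsv"), "KO1")
  expect_true(all(c("feature_id", "lfc", "fdr") %in% names(de)))
  truth <- read_truth_json(file.path(d, "truth.json"))
  expect_equal(
    as.data.frame(truth$island_intervals),
    as.data.frame(read_truth_json(file.path(d, "truth.json"))$island_intervals))
})

test_that("planted truth serializes to JSON and round-trips losslessly", {
  fx <- small_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(fx$gen$truth, path)
  back <- read_truth_json(path)
  expect_equal(as.data.frame(fx$gen$truth$island_intervals),
               as.data.frame(back$island_intervals))
  expect_equal(unname(fx$gen$truth$levels), unname(back$levels))
  expect_equal(fx$gen$truth$upregulated_te_ids, back$upregulated_te_ids)
  expect_equal(fx$gen$truth$true_lfc, back$true_lfc, tolerance = 1e-12)
})

test_that("knockout island methylation concentrates at level / depletion", {
  # Monte-Carlo check of the sampling model: pooled island counts in a KO
  # should estimate island_level / depletion within 3 binomial SEs
  fx <- small_fixture()
  cfg <- fx$cfg
  expected <- cfg$island_cg_methylation / cfg$ko_depletion_factor
  isl <- fx$gen$truth$island_intervals
  for (ko in cfg$sample_ids[2:3]) {
    r <- region_methylation(fx$samples[[ko]], isl[1], "CG")
    expect_gt(r$n_total, 2000) # enough read draws for a tight MC bound
    se <- sqrt(expected * (1 - expected) / r$n_total)
    expect_lt(abs(r$level - expected), 3 * se + 1e-6)
  }
})

test_that("per-island empirical methylation converges to planted truth", {
  fx <- small_fixture()
  truth <- fx$gen$truth
  for (i in seq_along(truth$island_intervals)) {
    for (sid in fx$cfg$sample_ids) {
      r <- region_methylation(fx$samples[[sid]], truth$island_intervals[i],
                              "CG")
      lvl <- truth$levels[i, sid]
      se <- sqrt(lvl * (1 - lvl) / r$n_total)
      expect_lt(abs(r$level - lvl), 3 * se,
                label = sprintf("island %d sample %s", i, sid))
    }
  }
})

test_that("emitted contexts match an independent re-scan of the genome", {
  fx <- small_fixture()
  seq1 <- as.character(fx$gen$genome[[1]])
  # re-scan a 2-kb window straddling an island edge
  st <- GenomicRanges::start(fx$gen$truth$island_intervals[1]) - 1000L
  win <- substr(seq1, st, st + 1999L)
  oracle <- brute_context_scan(win)
  # the oracle cannot see past the window edges; compare interior positions
  oracle <- oracle[oracle$pos >= 3 & oracle$pos <= 1998, ]
  oracle$pos <- oracle$pos + st - 1L
  rec <- fx$samples$WT$records
  sub <- rec[rec$chrom == names(fx$gen$genome)[1] & rec$pos >= st + 2L &
               rec$pos <= st + 1997L]
  sub <- sub[order(sub$pos, sub$strand)]
  oracle <- oracle[order(oracle$pos, oracle$strand), ]
  expect_equal(nrow(sub), nrow(oracle))
  expect_equal(sub$context, oracle$context)
})

test_that("zero mean coverage yields a valid all-zero report", {
  cfg <- small_sim_config(seed = 12L, mean_coverage = 0)
  gen <- generate_genome(cfg)
  s <- simulate_methylome(gen$genome, gen$truth, "WT", cfg)
  expect_true(all(s$records$m + s$records$u == 0L))
  expect_equal(nrow(filter_by_coverage(list(s), 1, "CG")), 0L)
})

test_that("zero-noise planted expression reproduces the true LFC exactly", {
  cfg <- small_sim_config(seed = 31L, lfc_noise_sd = 0)
  gen <- generate_genome(cfg)
  de <- simulate_expression(gen$annotations, gen$truth, cfg)
  up <- gen$truth$upregulated_te_ids
  for (tab in de) {
    obs <- tab$log2FoldChange[match(up, tab$feature_id)]
    expect_equal(obs, unname(gen$truth$true_lfc[up]), tolerance = 1e-12)
    # unplanted features stay above the significance boundary
    unplanted <- setdiff(tab$feature_id, names(which(gen$truth$true_lfc != 0)))
    expect_true(all(tab$padj[match(unplanted, tab$feature_id)] >=
                      cfg$fdr_threshold))
  }
})

test_that("planted island contrast clears the DMR delta threshold", {
  cfg <- sim_config()
  planted_delta <- cfg$island_cg_methylation *
    (1 - 1 / cfg$ko_depletion_factor)
  expect_gt(planted_delta, 0.20)
  expect_equal(planted_delta, 0.8 * (1 - 1 / 4.5), tolerance = 1e-12)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(gc_content = 1.2), "gc_content")
  expect_error(sim_config(ko_depletion_factor = 0), "ko_depletion_factor")
  expect_error(sim_config(te_island_length_range = c(5000L, 2000L)),
               "increasing")
  expect_error(sim_config(te_island_length_range = c(2000L, 600001L)),
               "fit inside")
})
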