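write_report_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("cytosine reports parse with level arithmetic intact", {
  path <- write_report_lines(c(
    "chr1\t10\t+\t5\t15\tCG\tCGA",
    "chr1\t11\t-\t3\t1\tCG\tCGT",
    "chr2\t4\t+\t0\t0\tCHH\tCAT"))
  s <- read_cytosine_report(path, "s1")
  expect_equal(nrow(s$records), 3L)
  r <- s$records[1]
  expect_equal(r$m + r$u, 20L)
  expect_equal(r$m / (r$m + r$u), 0.25)
})

test_that("malformed report rows are rejected with their line number", {
  bad_count <- write_report_lines("chr1\t10\t+\t-2\t5\tCG\tCGA")
  expect_error(read_cytosine_report(bad_count), "line 1")
  bad_ctx <- write_report_lines(c("chr1\t10\t+\t1\t5\tCG\tCGA",
                                  "chr1\t12\t+\t1\t5\tCpG\tCGA"))
  expect_error(read_cytosine_report(bad_ctx), "line 2")
  dup <- write_report_lines(c("chr1\t10\t+\t1\t5\tCG\tCGA",
                              "chr1\t10\t+\t2\t5\tCG\tCGA"))
  expect_error(read_cytosine_report(dup), "duplicate")
})

test_that("context assignment follows the two-downstream-base rule", {
  ctx <- assign_contexts(c(s = "ACGT"))
  # C at +2 reads CG; the paired G at 3 is a CG cytosine on the minus strand
  expect_equal(ctx[ctx$pos == 2 & ctx$strand == "+"]$context, "CG")
  expect_equal(ctx[ctx$pos == 3 & ctx$strand == "-"]$context, "CG")
  ctx <- assign_contexts(c(s = "ACAGT"))
  expect_equal(ctx[ctx$pos == 2 & ctx$strand == "+"]$context, "CHG")
  ctx <- assign_contexts(c(s = "ACATT"))
  expect_equal(ctx[ctx$pos == 2 & ctx$strand == "+"]$context, "CHH")
  # truncated downstream sequence defaults to CHH
  ctx <- assign_contexts(c(s = "AAC"))
  expect_equal(ctx[ctx$pos == 3 & ctx$strand == "+"]$context, "CHH")
  expect_error(assign_contexts(c(s = "ACXT")), "non-ACGTN")
})

test_that("context assignment matches a brute-force scan on random sequence", {
  withr::local_seed(42)
  for (rep in 1:3) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 2000, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    got <- as.data.frame(assign_contexts(c(chr = seq))[, c("pos", "strand",
                                                           "context")])
    want <- brute_context_scan(seq)
    want <- want[order(want$pos, want$strand), ]
    got <- got[order(got$pos, got$strand), ]
    expect_equal(got$pos, want$pos)
    expect_equal(got$context, want$context)
  }
})

test_that("coverage filter keeps only positions covered in every sample", {
  mk <- function(cov, id) methylome(data.table::data.table(
    chrom = "c1", pos = seq_along(cov), strand = "+",
    m = 0L, u = as.integer(cov), context = "CG"), id)
  s1 <- mk(c(6, 6, 0), "a"); s2 <- mk(c(6, 4, 9), "b"); s3 <- mk(c(9, 6, 9), "c")
  kept <- filter_by_coverage(list(s1, s2, s3), 5, "CG")
  expect_equal(kept$pos, 1L) # pos 2 fails one sample, pos 3 fails another
  expect_equal(nrow(filter_by_coverage(list(s1, s2, s3), 0, "CG")), 3L)
})

test_that("raising the coverage threshold never adds positions", {
  fx <- small_fixture()
  sizes <- vapply(c(0, 5, 10, 20, 40), function(mc)
    nrow(filter_by_coverage(fx$samples, mc, "CG")), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  kept10 <- filter_by_coverage(fx$samples, 10, "CG")
  kept5 <- filter_by_coverage(fx$samples, 5, "CG")
  expect_equal(nrow(data.table::fintersect(kept10, kept5)), nrow(kept10))
})

test_that("region methylation equals the total-reads ratio", {
  s <- methylome(data.table::data.table(
    chrom = "c1", pos = c(5L, 9L, 30L), strand = c("+", "-", "+"),
    m = c(3L, 1L, 8L), u = c(1L, 3L, 2L), context = "CG"), "s")
  r <- region_methylation(s, list(chrom = "c1", start = 0, end = 20), "CG")
  expect_equal(r$level, 0.5) # (3+1)/(4+4)
  expect_equal(r$n_sites, 2L)
  r <- region_methylation(s, list(chrom = "c1", start = 25, end = 40), "CG")
  expect_equal(r$level, 0.8)
  # empty region reports missing, never zero
  r <- region_methylation(s, list(chrom = "c1", start = 100, end = 200), "CG")
  expect_true(is.na(r$level))
  expect_equal(r$n_sites, 0L)
})

test_that("region methylation agrees with per-row brute force on random data", {
  withr::local_seed(7)
  for (rep in 1:100) {
    rec <- random_records()
    s <- methylome(rec, "r")
    st <- sample.int(300, 1) - 1L; en <- st + sample.int(150, 1)
    got <- region_methylation(s, list(chrom = "c1", start = st, end = en),
                              "CG")
    want <- brute_region_meth(as.data.frame(rec), "c1", st, en, "CG")
    expect_identical(got[c("m_total", "n_total", "n_sites")],
                     want[c("m_total", "n_total", "n_sites")])
    expect_equal(got$level, want$level)
  }
})

test_that("region level is the coverage-weighted mean of site levels", {
  fx <- small_fixture()
  isl <- fx$gen$truth$island_intervals[2]
  r <- region_methylation(fx$samples$WT, isl, "CG")
  rec <- fx$samples$WT$records
  sub <- rec[rec$chrom == as.character(GenomeInfoDb::seqnames(isl)) &
               rec$pos >= GenomicRanges::start(isl) &
               rec$pos <= GenomicRanges::end(isl) & rec$context == "CG"]
  cov <- sub$m + sub$u
  site_level <- ifelse(cov > 0, sub$m / cov, 0)
  expect_equal(r$level, sum(site_level * cov) / sum(cov), tolerance = 1e-12)
})

test_that("feature methylation matrix separates islands from background", {
  fx <- small_fixture()
  tes <- fx$gen$annotations$tes
  mat <- feature_methylation_matrix(fx$samples, tes, "CG", fx$positions)
  expect_equal(dim(mat), c(length(tes), 3L))
  is_island <- S4Vectors::mcols(tes)$is_island
  cfg <- fx$cfg
  expect_true(all(abs(mat[is_island, "WT"] - cfg$island_cg_methylation) < 0.08))
  ko_level <- cfg$island_cg_methylation / cfg$ko_depletion_factor
  expect_true(all(abs(mat[is_island, c("KO1", "KO2")] - ko_level) < 0.08))
  expect_true(all(mat[!is_island, ] < 0.10))
})

test_that("bedGraph output converts to 0-based and round-trips levels", {
  s <- methylome(data.table::data.table(
    chrom = "chr1", pos = 10L, strand = "+", m = 1L, u = 1L,
    context = "CG"), "s")
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(s, path)
  lines <- readLines(path)
  expect_match(lines[1], "^track type=bedGraph")
  expect_equal(strsplit(lines[2], "\t")[[1]], c("chr1", "9", "10", "0.5"))
  # a fuller sample round-trips within float formatting
  fx <- small_fixture()
  p2 <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(fx$samples$WT, p2, "CG", fx$positions)
  tr <- data.table::fread(p2, skip = 1L,
                          col.names = c("chrom", "start", "end", "level"))
  rec <- merge(fx$samples$WT$records,
               fx$positions, by = c("chrom", "pos", "strand"))
  agg <- rec[, list(level = sum(m) / sum(m + u)), by = c("chrom", "pos")]
  data.table::setorder(agg, chrom, pos)
  expect_equal(tr$level, agg$level, tolerance = 1e-5)
})

test_that("BED annotations round-trip with TE family labels", {
  fx <- small_fixture()
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(fx$gen$annotations$tes, path)
  back <- read_bed_annotations(path, "TE", fx$lens)
  expect_equal(as.character(GenomeInfoDb::seqnames(back)),
               as.character(GenomeInfoDb::seqnames(fx$gen$annotations$tes)))
  expect_equal(GenomicRanges::start(back),
               GenomicRanges::start(fx$gen$annotations$tes))
  expect_equal(S4Vectors::mcols(back)$name,
               S4Vectors::mcols(fx$gen$annotations$tes)$name)
  expect_equal(S4Vectors::mcols(back)$family,
               S4Vectors::mcols(fx$gen$annotations$tes)$family)
})
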