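#' Tile a genome into fixed-width bins
#'
#' Per chromosome, bins cover `[0, w), [w, 2w), ...`; the final partial bin
#' keeps its true (shorter) length.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param width bin width in bp (default 100).
#' @return `GRanges` grid with seqlengths set.
#' @export
make_bins <- function(chrom_lengths, width = 100) {
  if (width < 1) stopf("bin width must be >= 1")
  chrom_lengths <- chrom_lengths[chrom_lengths > 0]
  if (!length(chrom_lengths)) return(GRanges())
  bins <- GenomicRanges::tileGenome(chrom_lengths, tilewidth = width,
                                    cut.last.tile.in.chrom = TRUE)
  names(bins) <- NULL
  bins
}

#' Per-bin methylation counts for a reference/treatment sample pair
#'
#' Sums methylated and total read counts per bin per sample over the retained
#' in-context cytosines of both strands. `n_cytosines` counts the retained
#' cytosines in the bin (the same set for both samples because the position
#' filter is shared); `n_meth_ref` counts retained reference cytosines with
#' at least `min_ref_meth_reads` methylated reads.
#'
#' @param bins `GRanges` grid from [make_bins()].
#' @param ref,treat [methylome] objects.
#' @param context context to aggregate (default `"CG"`).
#' @param positions position filter from [filter_by_coverage()]; should be
#'   computed over all samples of the study.
#' @param min_ref_meth_reads read support defining a "methylated" reference
#'   cytosine (default 1).
#' @return data.table with one row per bin: chrom, start (0-based), end,
#'   bin (index), m_ref, n_ref, m_treat, n_treat, n_cytosines, n_meth_ref.
#' @export
aggregate_counts <- function(bins, ref, treat, context = "CG",
                             positions = NULL, min_ref_meth_reads = 1L) {
  bdt <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(bins)),
    start = GenomicRanges::start(bins), # 1-based inclusive
    end = GenomicRanges::end(bins),
    bin = seq_along(bins))
  setkeyv(bdt, c("chrom", "start", "end"))
  sum_one <- function(sample) {
    dt <- retained_records(sample, positions, context)
    if (!nrow(dt))
      return(data.table(bin = integer(), m = integer(), n = integer(),
                        sites = integer(), meth_sites = integer()))
    site <- dt[, list(chrom, start = pos, end = pos, m, u)]
    setkeyv(site, c("chrom", "start", "end"))
    hits <- foverlaps(site, bdt, type = "within", nomatch = NULL)
    hits[, list(m = sum(m), n = sum(m + u), sites = .N,
                meth_sites = sum(m >= min_ref_meth_reads)), by = "bin"]
  }
  a <- sum_one(ref); b <- sum_one(treat)
  out <- bdt[, list(chrom, start = start - 1L, end, bin)]
  out <- merge(out, a[, list(bin, m_ref = m, n_ref = n, n_cytosines = sites,
                             n_meth_ref = meth_sites)],
               by = "bin", all.x = TRUE)
  out <- merge(out, b[, list(bin, m_treat = m, n_treat = n)],
               by = "bin", all.x = TRUE)
  for (col in c("m_ref", "n_ref", "m_treat", "n_treat", "n_cytosines",
                "n_meth_ref"))
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  setorder(out, bin)
  out[]
}

#' Two-proportion score test for a difference in methylation level
#'
#' Tests equality of methylation proportions between two read-count pools
#' using the pooled-variance standardized difference:
#' \deqn{z = \frac{m_1/n_1 - m_2/n_2}{\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},
#'   \qquad \hat p = \frac{m_1 + m_2}{n_1 + n_2},}
#' with a two-sided normal p-value. Conventions: if the pooled proportion is
#' 0 or 1 the variance vanishes and the result is z = 0, p = 1; if either
#' pool is empty (n = 0) the comparison is untestable and z and p are `NA`.
#' No continuity correction is applied.
#'
#' All arguments are vectorized.
#'
#' @param m1,n1 methylated and total read counts of the first sample.
#' @param m2,n2 counts of the second sample.
#' @return data.table with columns `z` and `p`.
#' @export
score_test <- function(m1, n1, m2, n2) {
  k <- max(length(m1), length(n1), length(m2), length(n2))
  m1 <- rep_len(as.numeric(m1), k); n1 <- rep_len(as.numeric(n1), k)
  m2 <- rep_len(as.numeric(m2), k); n2 <- rep_len(as.numeric(n2), k)
  if (any(m1 > n1, na.rm = TRUE) || any(m2 > n2, na.rm = TRUE))
    stopf("methylated counts exceed total counts")
  z <- rep(NA_real_, k); p <- rep(NA_real_, k)
  ok <- n1 > 0 & n2 > 0
  pool <- (m1 + m2) / (n1 + n2)
  degen <- ok & (pool <= 0 | pool >= 1)
  z[degen] <- 0; p[degen] <- 1
  i <- ok & !degen
  se <- sqrt(pool[i] * (1 - pool[i]) * (1 / n1[i] + 1 / n2[i]))
  z[i] <- (m1[i] / n1[i] - m2[i] / n2[i]) / se
  p[i] <- 2 * stats::pnorm(-abs(z[i]))
  data.table(z = z, p = p)
}

#' Call 100-bp differentially methylated regions between two methylomes
#'
#' For every bin of the genome grid, pools the retained in-context cytosine
#' read counts of each sample, applies the two-proportion [score_test()], and
#' calls the bin a DMR when the absolute level difference reaches
#' `min_delta` and the p-value is at or below `max_p`. Direction is `hypo`
#' when the reference level exceeds the treatment level (methylation lost in
#' the treatment). Hypomethylated calls additionally require at least
#' `min_ref_meth_cpg` methylated cytosines in the reference bin, which
#' separates regions of genuine methylation loss from isolated
#' differentially methylated cytosines. Bins where either sample has no
#' retained reads are untestable and skipped (their count is recorded in
#' the result's metadata).
#'
#' Defaults are the study parameters: 100-bp bins, CG context, an absolute
#' delta of at least 0.20, p < 0.01 (implemented as p <= max_p on the closed
#' boundary), and at least 2 methylated reference CpGs.
#'
#' @param ref reference [methylome] (e.g. wild type).
#' @param treat treatment [methylome] (e.g. knockout).
#' @param chrom_lengths named chromosome lengths (bp).
#' @param positions position filter from [filter_by_coverage()] computed over
#'   all study samples; if `NULL`, computed from `ref` and `treat` alone with
#'   `min_cov`.
#' @param bin_width bin width (bp).
#' @param context cytosine context.
#' @param min_cov per-sample coverage threshold used only when `positions`
#'   is `NULL`.
#' @param min_delta minimum absolute methylation difference.
#' @param max_p p-value threshold.
#' @param min_ref_meth_cpg minimum methylated reference cytosines for a
#'   hypoDMR.
#' @param min_ref_meth_reads read support defining "methylated" (default 1).
#' @param p_adjust p-value adjustment method (default `"none"`, matching the
#'   raw threshold the defaults encode; any [stats::p.adjust()] method).
#' @param merge_gap if non-`NULL`, adjacent same-direction DMR bins separated
#'   by less than `merge_gap` bp are merged into longer regions (off by
#'   default: DMRs are reported as fixed grid bins).
#' @return a `GRanges` of DMRs with metadata columns `direction`, `delta`,
#'   `level_ref`, `level_treat`, `z`, `p`, `score` (-log10 p),
#'   `n_cytosines`, `n_meth_ref`, `name`, `feature_class`; calling
#'   parameters and bin bookkeeping are in `metadata()`.
#' @export
call_dmrs <- function(ref, treat, chrom_lengths, positions = NULL,
                      bin_width = 100, context = "CG", min_cov = 5,
                      min_delta = 0.20, max_p = 0.01, min_ref_meth_cpg = 2,
                      min_ref_meth_reads = 1L, p_adjust = "none",
                      merge_gap = NULL) {
  stopifnot(min_delta >= 0, max_p > 0, max_p <= 1)
  if (is.null(positions))
    positions <- filter_by_coverage(list(ref, treat), min_cov, context)
  bins <- make_bins(chrom_lengths, bin_width)
  if (!nrow(positions)) {
    warnf("empty position filter: no cytosine passes coverage %sX in all samples",
          min_cov)
    empty <- GRanges(seqlengths = chrom_lengths)
    metadata(empty) <- list(params = dmr_params_list(environment()),
                            n_bins = length(bins), n_testable = 0L,
                            n_skipped = length(bins))
    return(empty)
  }
  cnt <- aggregate_counts(bins, ref, treat, context, positions,
                          min_ref_meth_reads)
  testable <- cnt$n_ref > 0 & cnt$n_treat > 0
  tc <- cnt[which(testable)]
  st <- score_test(tc$m_ref, tc$n_ref, tc$m_treat, tc$n_treat)
  tc[, `:=`(level_ref = m_ref / n_ref, level_treat = m_treat / n_treat)]
  tc[, `:=`(delta = level_ref - level_treat, z = st$z,
            p = stats::p.adjust(st$p, method = p_adjust))]
  call <- abs(tc$delta) >= min_delta & tc$p <= max_p & tc$n_cytosines >= 1
  hypo <- tc$delta > 0
  call <- call & (!hypo | tc$n_meth_ref >= min_ref_meth_cpg)
  dmr <- tc[which(call)]
  setorder(dmr, chrom, start)
  gr <- GRanges(dmr$chrom, IRanges(dmr$start + 1L, dmr$end),
                seqinfo = GenomeInfoDb::Seqinfo(names(chrom_lengths),
                                                unname(chrom_lengths)))
  mcols(gr) <- S4Vectors::DataFrame(
    direction = ifelse(dmr$delta > 0, "hypo", "hyper"),
    delta = dmr$delta, level_ref = dmr$level_ref,
    level_treat = dmr$level_treat, z = dmr$z, p = dmr$p,
    score = -log10(pmax(dmr$p, 1e-300)),
    n_cytosines = dmr$n_cytosines, n_meth_ref = dmr$n_meth_ref)
  mcols(gr)$name <- sprintf("DMR_%s_%d", as.character(GenomeInfoDb::seqnames(gr)),
                            GenomicRanges::start(gr) - 1L)
  mcols(gr)$feature_class <- rep("DMR", length(gr))
  if (!is.null(merge_gap)) gr <- merge_dmr_bins(gr, merge_gap)
  metadata(gr) <- list(params = dmr_params_list(environment()),
                       n_bins = length(bins),
                       n_testable = sum(testable),
                       n_skipped = sum(!testable))
  gr
}

dmr_params_list <- function(env) {
  lapply(stats::setNames(nm = c("bin_width", "context", "min_cov", "min_delta",
                                "max_p", "min_ref_meth_cpg",
                                "min_ref_meth_reads", "p_adjust")),
         function(nm) get(nm, envir = env))
}

merge_dmr_bins <- function(gr, gap) {
  if (!length(gr)) return(gr)
  out <- lapply(unique(mcols(gr)$direction), function(d) {
    g <- gr[mcols(gr)$direction == d]
    red <- GenomicRanges::reduce(g, min.gapwidth = gap)
    hit <- GenomicRanges::findOverlaps(red, g)
    agg <- data.table(r = queryHits(hit), p = mcols(g)$p[subjectHits(hit)],
                      delta = mcols(g)$delta[subjectHits(hit)])
    agg <- agg[, list(p = min(p), delta = mean(delta)), by = "r"]
    mcols(red) <- S4Vectors::DataFrame(direction = d, delta = agg$delta,
                                       p = agg$p,
                                       score = -log10(pmax(agg$p, 1e-300)))
    red
  })
  sort(do.call(c, out))
}

#' Consensus DMRs across two replicate comparisons
#'
#' The common set contains the bins (identical coordinates) called with the
#' requested direction in both inputs; shared fractions are reported
#' relative to each input, together with the input-specific complements
#' (the Venn partition).
#'
#' @param set_a,set_b DMR `GRanges` from [call_dmrs()] on the same bin grid.
#' @param direction direction to intersect (default `"hypo"`).
#' @return list with `common`, `a_only`, `b_only` (`GRanges`), `shared_a`,
#'   `shared_b` (fractions), `n_a`, `n_b`, `n_common`.
#' @export
consensus_dmrs <- function(set_a, set_b, direction = "hypo") {
  pa <- metadata(set_a)$params; pb <- metadata(set_b)$params
  if (!is.null(pa$bin_width) && !is.null(pb$bin_width) &&
      pa$bin_width != pb$bin_width)
    stopf("DMR sets use different bin grids (%d vs %d bp)",
          pa$bin_width, pb$bin_width)
  a <- set_a[mcols(set_a)$direction == direction]
  b <- set_b[mcols(set_b)$direction == direction]
  key <- function(g) paste0(as.character(GenomeInfoDb::seqnames(g)), ":",
                            GenomicRanges::start(g), "-", GenomicRanges::end(g),
                            recycle0 = TRUE)
  ka <- key(a); kb <- key(b)
  common <- a[ka %in% kb]
  mcols(common)$delta_b <- mcols(b)$delta[match(key(common), kb)]
  list(common = common, a_only = a[!ka %in% kb], b_only = b[!kb %in% ka],
       shared_a = if (length(a)) length(common) / length(a) else NA_real_,
       shared_b = if (length(b)) length(common) / length(b) else NA_real_,
       n_a = length(a), n_b = length(b), n_common = length(common))
}

#' Percent of the genome covered by a DMR set
#'
#' DMR bins are non-overlapping by grid construction, so the fraction is the
#' summed interval length over the summed chromosome lengths.
#'
#' @param dmrs DMR `GRanges`.
#' @param chrom_lengths named chromosome lengths (bp).
#' @return percent of the genome (0-100).
#' @export
genome_fraction <- function(dmrs, chrom_lengths) {
  total <- sum(as.numeric(chrom_lengths))
  if (total <= 0) stopf("total genome length must be positive")
  100 * sum(as.numeric(GenomicRanges::width(dmrs))) / total
}
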