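# Independent brute-force oracles used to cross-check the package's
# implementations on small random instances. These deliberately avoid the
# code paths they verify (plain loops, substr scans, full enumeration).

# Weighted methylation level of [start0, end) by per-row summation.
brute_region_meth <- function(records, chrom, start0, end, ctx = "CG") {
  m <- 0L; n <- 0L; k <- 0L
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$chrom == chrom && r$context == ctx &&
        r$pos >= start0 + 1 && r$pos <= end) {
      m <- m + r$m; n <- n + r$m + r$u; k <- k + 1L
    }
  }
  list(level = if (n > 0) m / n else NA_real_, m_total = m, n_total = n,
       n_sites = k)
}

# All-pairs interval overlap on 1-based closed coordinates (as GRanges).
brute_overlap_pairs <- function(q, s, min_bp = 1) {
  qs <- as.data.frame(q); ss <- as.data.frame(s)
  out <- NULL
  for (i in seq_len(nrow(qs))) for (j in seq_len(nrow(ss))) {
    if (qs$seqnames[i] != ss$seqnames[j]) next
    ov <- min(qs$end[i], ss$end[j]) - max(qs$start[i], ss$start[j]) + 1
    if (ov >= min_bp) out <- rbind(out, c(i, j, ov))
  }
  if (is.null(out)) return(data.frame(query = integer(), subject = integer(),
                                      overlap_bp = integer()))
  out <- as.data.frame(out)
  names(out) <- c("query", "subject", "overlap_bp")
  out[] <- lapply(out, as.integer)
  out <- out[order(out$query, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-position context call by direct substring inspection.
brute_context_scan <- function(seq) {
  n <- nchar(seq)
  base <- function(i) if (i >= 1 && i <= n) substr(seq, i, i) else "N"
  out <- NULL
  for (i in seq_len(n)) {
    b <- base(i)
    if (b == "C") {
      ctx <- if (base(i + 1) == "G") "CG"
             else if (base(i + 2) == "G") "CHG" else "CHH"
      out <- rbind(out, data.frame(pos = i, strand = "+", context = ctx))
    }
    if (b == "G") {
      ctx <- if (base(i - 1) == "C") "CG"
             else if (base(i - 2) == "C") "CHG" else "CHH"
      out <- rbind(out, data.frame(pos = i, strand = "-", context = ctx))
    }
  }
  out
}

# Exact two-sided rank-sum p by full enumeration over all C(n1+n2, n1)
# assignments of ranks to the first sample (tie-free data only).
enum_wilcoxon_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  W <- sum(rank(c(x, y))[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  combos <- utils::combn(N, n1)
  Ws <- colSums(matrix(seq_len(N)[combos], nrow = n1))
  list(W = W, p = mean(abs(Ws - mu) >= abs(W - mu) - 1e-9))
}

# Pooled two-proportion z via an unrelated route: the continuity-uncorrected
# chi-square test statistic, signed by the observed difference.
prop_test_z <- function(m1, n1, m2, n2) {
  stat <- suppressWarnings(stats::prop.test(c(m1, m2), c(n1, n2),
                                            correct = FALSE)$statistic)
  unname(sign(m1 / n1 - m2 / n2) * sqrt(stat))
}

# Random small methylome record table for oracle tests.
random_records <- function(n_sites = 50, chroms = c("c1", "c2"), span = 400) {
  data.table::data.table(
    chrom = sample(chroms, n_sites, replace = TRUE),
    pos = sample.int(span, n_sites, replace = TRUE),
    strand = sample(c("+", "-"), n_sites, replace = TRUE),
    m = rpois(n_sites, 3),
    u = rpois(n_sites, 5),
    context = sample(c("CG", "CHG", "CHH"), n_sites, replace = TRUE,
                     prob = c(0.6, 0.2, 0.2))
  )[!duplicated(paste(chrom, pos, strand))]
}

random_granges <- function(n, chroms = c("c1", "c2"), span = 1000,
                           max_len = 80) {
  st <- sample.int(span, n, replace = TRUE)
  GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                         IRanges::IRanges(st, st + sample.int(max_len, n,
                                                              replace = TRUE)))
}
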