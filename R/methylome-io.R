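#' Construct a methylome sample from per-cytosine records
#'
#' A methylome sample holds one line's per-cytosine methylated/unmethylated
#' read counts. Records are stored 1-based (Bismark cytosine-report dialect),
#' per strand, sorted by (chrom, pos, strand); duplicate positions are an
#' error because they would double-count reads in every downstream sum.
#'
#' @param records data.frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`+`/`-`), `m` (methylated reads), `u` (unmethylated reads), `context`
#'   (`CG`/`CHG`/`CHH`) and optionally `tri` (strand trinucleotide).
#' @param sample_id sample label.
#' @return an object of class `methylome`.
#' @export
methylome <- function(records, sample_id) {
  dt <- as.data.table(records)
  need <- c("chrom", "pos", "strand", "m", "u", "context")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stopf("missing record columns: %s", paste(miss, collapse = ", "))
  if (nrow(dt)) {
    if (any(dt$m < 0 | dt$u < 0)) stopf("negative read counts")
    if (!all(dt$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
    bad <- setdiff(unique(dt$context), c("CG", "CHG", "CHH"))
    if (length(bad)) stopf("unknown context token(s): %s", paste(bad, collapse = ", "))
    if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
      stopf("duplicate (chrom, pos, strand) records in sample '%s'", sample_id)
  }
  dt[, `:=`(pos = as.integer(pos), m = as.integer(m), u = as.integer(u))]
  setkeyv(dt, c("chrom", "pos", "strand"))
  structure(list(sample_id = sample_id, records = dt[]), class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("methylome sample '%s': %d cytosines on %d sequence(s)\n",
              x$sample_id, nrow(x$records), length(unique(x$records$chrom))))
  ctx <- x$records[, .N, by = "context"]
  if (nrow(ctx)) cat(paste(sprintf("  %s: %d", ctx$context, ctx$N), collapse = "\n"), "\n")
  invisible(x)
}

#' Read a Bismark-style per-cytosine report
#'
#' Expects seven tab-separated columns without header: chrom, 1-based
#' position, strand, methylated count, unmethylated count, context
#' (CG/CHG/CHH), trinucleotide. Malformed rows are reported with their line
#' number; duplicated positions are rejected.
#'
#' @param path path to the report.
#' @param sample_id sample label; defaults to the file name without extension.
#' @return a [methylome] object.
#' @export
read_cytosine_report <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
              fill = TRUE)
  if (nrow(dt) && ncol(dt) != 7L)
    stopf("%s: expected 7 columns, found %d", path, ncol(dt))
  if (!nrow(dt))
    return(methylome(data.table(chrom = character(), pos = integer(),
                                strand = character(), m = integer(),
                                u = integer(), context = character(),
                                tri = character()), sample_id))
  setnames(dt, c("chrom", "pos", "strand", "m", "u", "context", "tri"))
  for (col in c("pos", "m", "u")) {
    v <- suppressWarnings(as.integer(dt[[col]]))
    bad <- which(is.na(v) | v < 0 | (col == "pos" & v < 1))
    if (length(bad))
      stopf("%s line %d: invalid %s value '%s'", path, bad[1], col,
            dt[[col]][bad[1]])
    data.table::set(dt, j = col, value = v)
  }
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) stopf("%s line %d: invalid strand '%s'", path, bad[1], dt$strand[bad[1]])
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad)) stopf("%s line %d: unknown context '%s'", path, bad[1], dt$context[bad[1]])
  methylome(dt, sample_id)
}

#' Write a per-cytosine report in the seven-column dialect read by
#' [read_cytosine_report()]
#'
#' @param sample a [methylome].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sample, path) {
  dt <- sample$records
  out <- dt[, list(chrom, pos, strand, m, u, context,
                   tri = if ("tri" %in% names(dt)) tri else "NNN")]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign CG/CHG/CHH context to every cytosine of a genome
#'
#' Scans both strands: every C on the plus strand and every G on the minus
#' strand (a cytosine read 5'->3' on that strand) is classified by the next
#' one or two bases in the strand's reading direction: CG if the next base is
#' G, CHG if the base after next is G, otherwise CHH (H = A, C or T). N bases
#' count as H, and cytosines within 2 bp of a contig end with insufficient
#' downstream sequence default to CHH.
#'
#' @param genome a `DNAStringSet` (or named character vector of sequences).
#' @return data.table with columns chrom, pos (1-based), strand, context,
#'   tri (trinucleotide on the cytosine's strand, N-padded at contig ends).
#' @export
assign_contexts <- function(genome) {
  if (is.character(genome)) {
    bad <- grepl("[^ACGTNacgtn]", genome)
    if (any(bad))
      stopf("sequence '%s' contains non-ACGTN characters",
            (names(genome) %||% as.character(seq_along(genome)))[which(bad)[1]])
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (is.null(names(genome)) || anyNA(names(genome)))
    stopf("genome sequences must be named")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    s <- toupper(as.character(genome[[i]]))
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(bad <- setdiff(unique(ch), names(comp))))
      stopf("sequence '%s' contains non-ACGTN characters: %s",
            names(genome)[i], paste(bad, collapse = ","))
    n <- length(ch)
    # out-of-range lookups (contig ends) read as N, i.e. as H
    at <- function(idx) {
      v <- rep("N", length(idx))
      ok <- idx >= 1L & idx <= n
      v[ok] <- ch[idx[ok]]
      v
    }
    # plus strand: cytosine is a literal C; read rightwards
    ip <- which(ch == "C")
    b1 <- at(ip + 1L); b2 <- at(ip + 2L)
    ctx_p <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
    tri_p <- paste0("C", b1, b2, recycle0 = TRUE)
    # minus strand: cytosine appears as G on the reference; read leftwards,
    # complementing (next base on the minus strand pairs with pos - 1)
    im <- which(ch == "G")
    c1 <- at(im - 1L); c2 <- at(im - 2L)
    ctx_m <- ifelse(c1 == "C", "CG", ifelse(c2 == "C", "CHG", "CHH"))
    tri_m <- paste0("C", unname(comp[c1]), unname(comp[c2]), recycle0 = TRUE)
    out[[i]] <- data.table(
      chrom = names(genome)[i],
      pos = c(ip, im),
      strand = c(rep("+", length(ip)), rep("-", length(im))),
      context = c(ctx_p, ctx_m),
      tri = c(tri_p, tri_m))
  }
  res <- rbindlist(out)
  setkeyv(res, c("chrom", "pos", "strand"))
  res[]
}

#' Keep cytosine positions covered in every sample
#'
#' Implements the study-wide coverage filter: a position is retained only if
#' its read coverage (m + u) reaches `min_cov` in every supplied sample and
#' its context matches. The returned key is used by all downstream
#' region/bin summaries so that every sample is quantified over the same
#' cytosines.
#'
#' @param samples list of [methylome] objects.
#' @param min_cov minimum coverage per sample (reads); the study default is 5.
#' @param context context to retain, or `NULL` for all contexts.
#' @return data.table key of (chrom, pos, strand) sorted rows.
#' @export
filter_by_coverage <- function(samples, min_cov = 5, context = "CG") {
  stopifnot(length(samples) >= 1L, min_cov >= 0)
  keep <- NULL
  for (s in samples) {
    dt <- s$records
    if (!is.null(context)) {
      idx <- which(dt[["context"]] == context)
      dt <- dt[idx]
    }
    dt <- dt[which(dt[["m"]] + dt[["u"]] >= min_cov), c("chrom", "pos", "strand")]
    keep <- if (is.null(keep)) dt else merge(keep, dt,
      by = c("chrom", "pos", "strand"))
  }
  setkeyv(keep, c("chrom", "pos", "strand"))
  unique(keep)[]
}

# Subset a sample's records to a position filter (NULL = no filtering) and,
# optionally, to one context.
retained_records <- function(sample, positions = NULL, context = NULL) {
  dt <- sample$records
  if (!is.null(context)) {
    idx <- which(dt[["context"]] == context)
    dt <- dt[idx]
  }
  if (!is.null(positions)) dt <- merge(dt, positions,
    by = c("chrom", "pos", "strand"))
  dt
}

#' Weighted methylation level of a genomic region
#'
#' The weighted level is the total methylated read count divided by the total
#' read count over the region's in-context cytosines on both strands. A
#' region with no covered cytosines yields `NA`, never 0: absence of evidence
#' is propagated as missing.
#'
#' @param sample a [methylome].
#' @param region a length-1 `GRanges`, or a list/vector with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param context context to aggregate (default `"CG"`).
#' @param positions optional position filter from [filter_by_coverage()].
#' @return list with `level` (fraction or `NA`), `m_total`, `n_total`,
#'   `n_sites`.
#' @export
region_methylation <- function(sample, region, context = "CG",
                               positions = NULL) {
  r <- as_region(region)
  dt <- retained_records(sample, positions, context)
  # 0-based half-open [start, end) holds 1-based positions start+1 .. end
  dt <- dt[dt$chrom == r$chrom & dt$pos >= r$start + 1L & dt$pos <= r$end]
  m <- sum(dt$m); n <- sum(dt$m + dt$u)
  list(level = if (n > 0) m / n else NA_real_,
       m_total = m, n_total = n, n_sites = nrow(dt))
}

as_region <- function(region) {
  if (methods::is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    list(chrom = as.character(GenomeInfoDb::seqnames(region)),
         start = GenomicRanges::start(region) - 1L,
         end = GenomicRanges::end(region))
  } else {
    r <- as.list(region)
    stopifnot(all(c("chrom", "start", "end") %in% names(r)))
    r$start <- as.integer(r$start); r$end <- as.integer(r$end)
    if (r$start < 0 || r$start >= r$end) stopf("invalid region")
    r
  }
}

#' Feature-by-sample weighted methylation matrix
#'
#' One row per feature, one column per sample; each cell is the weighted
#' methylation level of the feature in that sample ([region_methylation()]);
#' cells without covered cytosines are `NA`.
#'
#' @param samples list of [methylome] objects.
#' @param features `GRanges` with a `name` metadata column (0-based half-open).
#' @param context context to aggregate.
#' @param positions optional position filter.
#' @return numeric matrix, rownames = feature names, colnames = sample ids.
#' @export
feature_methylation_matrix <- function(samples, features, context = "CG",
                                       positions = NULL) {
  stopifnot(length(features) > 0L)
  fdt <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(features)),
    start = GenomicRanges::start(features), # 1-based inclusive
    end = GenomicRanges::end(features),
    row = seq_along(features))
  setkeyv(fdt, c("chrom", "start", "end"))
  mat <- matrix(NA_real_, nrow = length(features), ncol = length(samples),
                dimnames = list(mcols(features)$name %||%
                                  as.character(seq_along(features)),
                                vapply(samples, `[[`, "", "sample_id")))
  for (j in seq_along(samples)) {
    dt <- retained_records(samples[[j]], positions, context)
    if (!nrow(dt)) next
    site <- dt[, list(chrom, start = pos, end = pos, m, u)]
    setkeyv(site, c("chrom", "start", "end"))
    hits <- foverlaps(site, fdt, type = "within", nomatch = NULL)
    if (!nrow(hits)) next
    agg <- hits[, list(m = sum(m), n = sum(m + u)), by = "row"]
    mat[agg$row, j] <- ifelse(agg$n > 0, agg$m / agg$n, NA_real_)
  }
  mat
}

#' Write per-cytosine methylation levels as a bedGraph track
#'
#' One line per retained cytosine: chrom, pos-1, pos, level (methylated /
#' total reads), sorted by position. Zero-coverage cytosines are omitted
#' (their level is undefined).
#'
#' @param sample a [methylome].
#' @param path output path.
#' @param context context to emit, or `NULL` for all.
#' @param positions optional position filter.
#' @param track_name track header name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(sample, path, context = "CG", positions = NULL,
                           track_name = sample$sample_id) {
  dt <- retained_records(sample, positions, context)
  dt <- dt[(dt$m + dt$u) > 0]
  setorder(dt, chrom, pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  if (nrow(dt))
    writeLines(sprintf("%s\t%d\t%d\t%.6g", dt$chrom, dt$pos - 1L, dt$pos,
                       dt$m / (dt$m + dt$u)), con)
  invisible(path)
}

#' Read a BED6 annotation file as a typed GRanges
#'
#' When the BED name field carries `id|family` pairs (written for TEs and
#' TE-genes), the two parts are split into `name` and `family` metadata
#' columns so ids stay joinable with expression tables.
#'
#' @param path BED file path.
#' @param feature_class one of gene, TE, TE_gene, peak, DMR, island.
#' @param chrom_lengths optional named lengths to set as seqlengths.
#' @return `GRanges` with `name`, `feature_class` and (for TEs) `family`.
#' @export
read_bed_annotations <- function(path, feature_class = c("gene", "TE",
                                 "TE_gene", "peak", "DMR", "island"),
                                 chrom_lengths = NULL) {
  feature_class <- match.arg(feature_class)
  gr <- rtracklayer::import(path, format = "BED")
  nm <- mcols(gr)$name %||% as.character(seq_along(gr))
  if (any(grepl("|", nm, fixed = TRUE))) {
    parts <- data.table::tstrsplit(nm, "|", fixed = TRUE)
    mcols(gr)$name <- parts[[1]]
    mcols(gr)$family <- if (length(parts) > 1) parts[[2]] else NA_character_
  } else {
    mcols(gr)$name <- nm
  }
  mcols(gr)$feature_class <- feature_class
  if (!is.null(chrom_lengths))
    GenomeInfoDb::seqlengths(gr) <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Write a GRanges as BED6
#'
#' Coordinates are converted to BED's 0-based half-open convention. TE
#' features with a `family` column are written as `id|family` in the name
#' field; a `score` metadata column (e.g. -log10 p for DMRs) is passed
#' through, defaulting to 0.
#'
#' @param gr `GRanges` with `name` metadata.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- mcols(gr)$name %||% as.character(seq_along(gr))
  fam <- mcols(gr)$family
  if (!is.null(fam)) nm <- ifelse(is.na(fam), nm, paste0(nm, "|", fam))
  sc <- mcols(gr)$score %||% rep(0, length(gr))
  dt <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm, score = round(sc, 4),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*", ".",
                    as.character(GenomicRanges::strand(gr))))
  setorder(dt, chrom, start)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
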