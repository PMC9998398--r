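#' All query/subject interval overlaps of at least `min_bp` base pairs
#'
#' bedtools-intersect semantics on half-open coordinates: two intervals
#' overlap when they share at least `min_bp` bases; strand is ignored. Pairs
#' are returned in deterministic order (query, then subject, by coordinate
#' of appearance).
#'
#' @param query,subject `GRanges`.
#' @param min_bp minimum overlap in bp (default 1).
#' @return list with `pairs` (data.table: `query`, `subject` indices,
#'   `overlap_bp`) and `query_hit` (logical per query interval).
#' @export
interval_overlap <- function(query, subject, min_bp = 1) {
  stopifnot(min_bp >= 1)
  hits <- GenomicRanges::findOverlaps(query, subject, minoverlap = min_bp,
                                      ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  ov <- GenomicRanges::pintersect(query[q], subject[s], ignore.strand = TRUE)
  pairs <- data.table(query = q, subject = s,
                      overlap_bp = GenomicRanges::width(ov))
  setorder(pairs, query, subject)
  list(pairs = pairs,
       query_hit = seq_along(query) %in% q)
}

# Extend intervals by `window` bp on both sides, clipping at 0 and at the
# chromosome length.
extend_clip <- function(gr, window, chrom_lengths = NULL) {
  if (window < 0) stopf("window must be >= 0")
  if (is.null(chrom_lengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (!any(is.na(sl))) chrom_lengths <- sl
  }
  st <- pmax(1L, GenomicRanges::start(gr) - as.integer(window))
  en <- GenomicRanges::end(gr) + as.integer(window)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[as.character(GenomeInfoDb::seqnames(gr))]
    en <- pmin(en, as.integer(lim))
  }
  GenomicRanges::ranges(gr) <- IRanges(st, en)
  gr
}

#' Feature hits within a window of a DMR set
#'
#' A feature counts as hit when its coordinates, extended by `window` bp
#' upstream and downstream (clipped at chromosome bounds), overlap at least
#' one DMR by >= 1 bp. `window = 0` reduces to direct overlap. This realizes
#' the regulatory-region analyses in which gene/TE coordinates are extended
#' by 500 bp or 1 kb.
#'
#' @param features `GRanges` with a `name` column.
#' @param dmrs `GRanges` of DMRs.
#' @param window extension in bp (>= 0).
#' @param chrom_lengths named chromosome lengths for right-clipping; taken
#'   from `seqlengths(features)` when `NULL`.
#' @return list with `hit` (logical per feature), `hit_ids` (names),
#'   `n_hit`, `percent` (hits / #features * 100).
#' @export
windowed_overlap <- function(features, dmrs, window = 0,
                             chrom_lengths = NULL) {
  ext <- extend_clip(features, window, chrom_lengths)
  hit <- IRanges::overlapsAny(ext, dmrs, minoverlap = 1L,
                                    ignore.strand = TRUE)
  ids <- (mcols(features)$name %||% as.character(seq_along(features)))[hit]
  list(hit = hit, hit_ids = ids, n_hit = sum(hit),
       percent = if (length(features)) 100 * sum(hit) / length(features)
                 else NA_real_)
}

#' DMR membership across labelled peak sets with exclusive combination counts
#'
#' Builds the boolean membership matrix of DMRs against each peak set
#' (>= 1 bp overlap) and tallies every exclusive combination pattern (UpSet
#' semantics: each DMR contributes to exactly one pattern, including the
#' all-zero "none" class) as well as the per-set marginal totals.
#'
#' @param dmrs `GRanges`.
#' @param peak_sets named list of `GRanges`, one per histone mark.
#' @return list with `matrix` (logical, DMRs x sets), `combination_counts`
#'   (named integer; names like `"H3K9me2+H3K9me3"`, `"none"`), `marginals`
#'   (named integer per set).
#' @export
histone_membership <- function(dmrs, peak_sets) {
  stopifnot(length(peak_sets) >= 1L)
  labels <- names(peak_sets)
  if (is.null(labels) || any(!nzchar(labels)))
    stopf("peak sets must be named")
  if (anyDuplicated(labels)) stopf("duplicate peak-set labels")
  m <- vapply(peak_sets, function(pk)
    IRanges::overlapsAny(dmrs, pk, minoverlap = 1L,
                               ignore.strand = TRUE),
    logical(length(dmrs)))
  if (length(dmrs) == 1L) m <- matrix(m, nrow = 1,
                                      dimnames = list(NULL, labels))
  if (length(dmrs) == 0L) m <- matrix(logical(), nrow = 0, ncol = length(labels),
                                      dimnames = list(NULL, labels))
  rownames(m) <- mcols(dmrs)$name %||% as.character(seq_len(nrow(m)))
  pattern <- apply(m, 1L, function(r)
    if (any(r)) paste(labels[r], collapse = "+") else "none")
  combo <- table(factor(pattern))
  list(matrix = m,
       combination_counts = stats::setNames(as.integer(combo), names(combo)),
       marginals = colSums(m))
}

#' Per-family counts of hit transposable elements
#'
#' Counts hit TEs by family and discards families represented by fewer than
#' `min_members` hit elements; the complement (TEs not hit) is summarized the
#' same way.
#'
#' @param te_hits character vector of hit TE ids.
#' @param family_map named character vector mapping TE id to family; ids
#'   without a family are assigned `"unknown"` (with a message).
#' @param min_members minimum family size among hits to retain (default 3).
#' @param all_te_ids optional universe of TE ids; defaults to
#'   `names(family_map)`. TEs not in `te_hits` form the complement.
#' @return list with `hit` and `non_hit` data.tables (`family`, `count`).
#' @export
summarize_te_families <- function(te_hits, family_map, min_members = 3,
                                  all_te_ids = names(family_map)) {
  fam_of <- function(ids) {
    f <- family_map[ids]
    nas <- is.na(f) | !nzchar(f)
    if (any(nas)) {
      message(sum(nas), " TE(s) without family assigned 'unknown'")
      f[nas] <- "unknown"
    }
    unname(f)
  }
  count_tab <- function(ids) {
    if (!length(ids)) return(data.table(family = character(), count = integer()))
    tab <- as.data.table(table(family = fam_of(ids)))
    setnames(tab, c("family", "count"))
    tab[, count := as.integer(count)]
    out <- tab[which(tab[["count"]] >= min_members)]
    setorder(out, -count, family)
    out[]
  }
  list(hit = count_tab(intersect(te_hits, all_te_ids)),
       non_hit = count_tab(setdiff(all_te_ids, te_hits)))
}
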