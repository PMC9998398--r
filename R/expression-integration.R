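#' Read a differential-expression summary table
#'
#' Consumes DESeq2-style output: a TSV with header columns `feature_id`,
#' `log2FoldChange`, `padj` (extra columns are ignored). Missing adjusted
#' p-values (`NA`) are tolerated and classified later as not significant.
#'
#' @param path TSV path.
#' @param mutant_label label of the mutant line the table belongs to.
#' @return data.table with `feature_id`, `lfc`, `fdr`, `mutant`.
#' @export
read_de_table <- function(path, mutant_label) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- fread(path, sep = "\t", na.strings = c("NA", ""))
  need <- c("feature_id", "log2FoldChange", "padj")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(dt[["feature_id"]]))
    stopf("%s: duplicate feature_id values", path)
  bad <- which(!is.na(dt[["padj"]]) & (dt[["padj"]] < 0 | dt[["padj"]] > 1))
  if (length(bad)) stopf("%s: padj outside [0,1] at row %d", path, bad[1])
  out <- dt[, list(feature_id = as.character(feature_id),
                   lfc = as.numeric(log2FoldChange),
                   fdr = as.numeric(padj))]
  out[, mutant := mutant_label]
  out[]
}

#' Classify differential expression per mutant and build consensus sets
#'
#' Per mutant, each feature falls in exactly one category under strict
#' thresholds: `upregulated` (lfc > lfc_thr and fdr < fdr_thr),
#' `downregulated` (lfc < -lfc_thr and fdr < fdr_thr), `stable`
#' (-lfc_thr < lfc < lfc_thr and fdr < fdr_thr: significant but small
#' change, taken literally), else `not_significant` (including missing fdr
#' and |lfc| exactly at the threshold). Consensus sets intersect/difference
#' the two mutants' categories.
#'
#' @param tables list of two data.tables from [read_de_table()], one per
#'   mutant.
#' @param lfc_thr absolute log2-fold-change threshold (> 0; default 1).
#' @param fdr_thr FDR threshold in (0, 1] (default 0.01; the study also
#'   reports some sets at 0.05 - always check the threshold echoed in
#'   report headers).
#' @return object of class `expression_classification`: list with `table`
#'   (feature_id, per-mutant lfc/fdr/category), `sets` (named list of id
#'   vectors: up_both, up_<A>_only, up_<B>_only, down_both, down_<A>_only,
#'   down_<B>_only, stable_both), `mutants`, `lfc_thr`, `fdr_thr`.
#' @export
classify_expression <- function(tables, lfc_thr = 1, fdr_thr = 0.01) {
  stopifnot(length(tables) == 2L, lfc_thr > 0, fdr_thr > 0, fdr_thr <= 1)
  tables <- lapply(seq_along(tables), function(i) {
    tb <- as.data.table(tables[[i]])
    if ("log2FoldChange" %in% names(tb))
      setnames(tb, c("log2FoldChange", "padj"), c("lfc", "fdr"),
               skip_absent = TRUE)
    if (!"mutant" %in% names(tb)) {
      lbl <- names(tables)[i] %||% paste0("mutant", i)
      tb[, mutant := lbl]
    }
    tb
  })
  mutants <- vapply(tables, function(t) t$mutant[1], "")
  if (anyDuplicated(mutants)) stopf("the two tables carry the same mutant label")
  categorize <- function(lfc, fdr) {
    sig <- !is.na(fdr) & fdr < fdr_thr
    ifelse(!sig, "not_significant",
      ifelse(lfc > lfc_thr, "upregulated",
        ifelse(lfc < -lfc_thr, "downregulated",
          ifelse(abs(lfc) < lfc_thr, "stable", "not_significant"))))
  }
  a <- copy(tables[[1]]); b <- copy(tables[[2]])
  a[, category := categorize(lfc, fdr)]
  b[, category := categorize(lfc, fdr)]
  wide <- merge(
    a[, list(feature_id, lfc_a = lfc, fdr_a = fdr, category_a = category)],
    b[, list(feature_id, lfc_b = lfc, fdr_b = fdr, category_b = category)],
    by = "feature_id", all = TRUE)
  for (col in c("category_a", "category_b"))
    data.table::set(wide, which(is.na(wide[[col]])), col, "not_significant")
  ids <- function(cond) wide$feature_id[cond]
  up_a <- wide$category_a == "upregulated"; up_b <- wide$category_b == "upregulated"
  dn_a <- wide$category_a == "downregulated"; dn_b <- wide$category_b == "downregulated"
  st_a <- wide$category_a == "stable"; st_b <- wide$category_b == "stable"
  sets <- list(ids(up_a & up_b), ids(up_a & !up_b), ids(up_b & !up_a),
               ids(dn_a & dn_b), ids(dn_a & !dn_b), ids(dn_b & !dn_a),
               ids(st_a & st_b))
  names(sets) <- c("up_both", paste0("up_", mutants[1], "_only"),
                   paste0("up_", mutants[2], "_only"), "down_both",
                   paste0("down_", mutants[1], "_only"),
                   paste0("down_", mutants[2], "_only"), "stable_both")
  structure(list(table = wide, sets = sets, mutants = mutants,
                 lfc_thr = lfc_thr, fdr_thr = fdr_thr),
            class = "expression_classification")
}

#' @export
print.expression_classification <- function(x, ...) {
  cat(sprintf("expression classification (|LFC| > %g, FDR < %g), mutants %s vs %s\n",
              x$lfc_thr, x$fdr_thr, x$mutants[1], x$mutants[2]))
  for (nm in names(x$sets)) cat(sprintf("  %-22s %d\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Mean-centered normalized log2 fold changes (z-scores)
#'
#' Standardizes LFC values over a stated feature subset using the sample
#' standard deviation (denominator n - 1), and flags strong responders
#' (z > 2). A constant LFC vector has no scale; all z are then `NA`.
#'
#' @param records data.table from [read_de_table()].
#' @param feature_subset ids defining the standardization population
#'   (default: all features in `records`); must contain >= 2 features.
#' @return data.table `feature_id`, `lfc`, `z`, `high` (z > 2).
#' @export
lfc_zscore <- function(records, feature_subset = NULL) {
  feature_subset <- feature_subset %||% records$feature_id
  idx <- which(records[["feature_id"]] %in% feature_subset)
  if (length(idx) < 2L) stopf("z-scores need a subset of >= 2 features")
  dt <- records[idx, list(feature_id, lfc)]
  s <- stats::sd(dt$lfc)
  if (is.na(s) || s == 0) {
    dt[, `:=`(z = NA_real_, high = NA)]
  } else {
    dt[, z := (lfc - mean(lfc)) / s]
    dt[, high := z > 2]
  }
  dt[]
}

#' Overlap of expression categories with consensus hypoDMRs across windows
#'
#' For each expression category (consensus up, per-mutant-only up, consensus
#' down, consensus stable) and each window size, reports the percentage of
#' the category's features whose (window-extended) coordinates overlap at
#' least one common hypoDMR. Consensus-upregulated features missed at window
#' 0 but hit once extended are reported separately as regulatory-region
#' attributions: their methylation loss lies in flanking sequence rather
#' than the feature body.
#'
#' @param classification an `expression_classification`.
#' @param common_hypodmrs `GRanges` of consensus hypoDMRs.
#' @param features `GRanges` with `name` matching classification feature ids;
#'   features restrict the analysis (e.g. TE-genes only).
#' @param windows integer vector of extensions in bp (default `c(0, 500, 1000)`).
#' @param chrom_lengths named lengths for window clipping.
#' @return list with `percent` (data.table: category, window, n_features,
#'   n_hit, percent) and `regulatory` (data.table: feature_id, window of
#'   first hit) for consensus-up features.
#' @export
link_dmr_expression <- function(classification, common_hypodmrs, features,
                                windows = c(0, 500, 1000),
                                chrom_lengths = NULL) {
  stopifnot(inherits(classification, "expression_classification"))
  if (any(windows < 0)) stopf("windows must be >= 0")
  windows <- sort(unique(as.integer(windows)))
  fname <- mcols(features)$name
  if (is.null(fname)) stopf("features need a 'name' metadata column")
  cats <- classification$sets[c("up_both",
                                grep("^up_.*_only$", names(classification$sets),
                                     value = TRUE),
                                "down_both", "stable_both")]
  all_cat_ids <- unique(unlist(cats))
  missing_coord <- setdiff(intersect(all_cat_ids,
                                     classification$table$feature_id),
                           fname)
  # features absent from the annotation set are simply outside the analysis
  # universe (e.g. plain genes when `features` is TE-genes only)
  rows <- list(); reg <- NULL; body_hit <- character()
  for (cat in names(cats)) {
    ids <- intersect(cats[[cat]], fname)
    sub <- features[fname %in% ids]
    for (w in windows) {
      ov <- windowed_overlap(sub, common_hypodmrs, w, chrom_lengths)
      rows[[length(rows) + 1L]] <- data.table(
        category = cat, window = w, n_features = length(sub),
        n_hit = ov$n_hit, percent = ov$percent)
      if (cat == "up_both") {
        if (w == 0L) {
          body_hit <- ov$hit_ids
        } else {
          new_hit <- setdiff(ov$hit_ids, c(body_hit,
                                           if (!is.null(reg)) reg$feature_id))
          if (length(new_hit))
            reg <- rbindlist(list(reg, data.table(feature_id = new_hit,
                                                  window = w)))
        }
      }
    }
  }
  list(percent = rbindlist(rows),
       regulatory = reg %||% data.table(feature_id = character(),
                                        window = integer()),
       missing_coordinates = missing_coord)
}

#' Wilcoxon rank-sum test with explicit rank-sum statistic
#'
#' Returns the rank-sum W of the first sample (midranks under ties) with a
#' two-sided p-value: exact when the pooled sample is small (n1 + n2 <= 12)
#' and tie-free, otherwise the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `statistic` (rank-sum of `x`), `p`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)])
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = W, p = unname(wt$p.value),
       method = if (exact) "exact" else "normal_approx")
}

#' Compare lengths of upregulated TEs by consensus-hypoDMR overlap
#'
#' Partitions consensus-upregulated TE features by direct (window 0) overlap
#' with common hypoDMRs and tests the two length distributions with
#' [wilcoxon_rank_sum()]. If a partition is empty, the test is undefined.
#'
#' @param up_features `GRanges` of consensus-upregulated TE features.
#' @param common_hypodmrs `GRanges`.
#' @return list with `len_overlap`, `len_no_overlap` (bp vectors) and
#'   `test` ([wilcoxon_rank_sum()] result, or `NULL` with a message when a
#'   partition is empty).
#' @export
compare_te_lengths <- function(up_features, common_hypodmrs) {
  hit <- IRanges::overlapsAny(up_features, common_hypodmrs,
                                    minoverlap = 1L, ignore.strand = TRUE)
  len <- GenomicRanges::width(up_features)
  a <- len[hit]; b <- len[!hit]
  test <- if (length(a) && length(b)) wilcoxon_rank_sum(a, b) else {
    message("one TE-length partition is empty; Wilcoxon p undefined")
    NULL
  }
  list(len_overlap = a, len_no_overlap = b, test = test)
}
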