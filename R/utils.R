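#' @importFrom data.table data.table as.data.table setkey setkeyv setorder
#'   fread fwrite := .N .SD setnames foverlaps rbindlist copy setattr
#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed from a master seed and a stream label
#'
#' Each randomised stage of the simulator draws from its own stream so that,
#' e.g., regenerating only the KO1 methylome reproduces it bit-for-bit without
#' replaying the genome or the other samples. The child seed is a polynomial
#' hash of the label folded into the master seed, kept below 2^31 so it is a
#' valid R integer seed.
#'
#' @param seed master integer seed.
#' @param label character stream label (e.g. a sample id).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, prime; keeps arithmetic exact in doubles
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  s <- (abs(seed) %% m + h * 7919) %% m
  as.integer(s %% (m - 2L) + 1L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

file_sha256 <- function(path) {
  vapply(path, function(p) digest::digest(file = p, algo = "sha256"),
         character(1), USE.NAMES = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Named integer vector of chromosome lengths from a genome or a GRanges.
chrom_lengths <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    stats::setNames(Biostrings::width(x), names(x))
  } else if (methods::is(x, "GRanges")) {
    sl <- GenomeInfoDb::seqlengths(x)
    if (any(is.na(sl))) stopf("GRanges has missing seqlengths")
    sl
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stopf("cannot derive chromosome lengths from a %s", class(x)[1])
  }
}
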