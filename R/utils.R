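# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats acf cor p.adjust pbinom prcomp rbinom rnorm rpois runif
#'   setNames wilcox.test dhyper t.test plogis rlnorm predict var
#' @importFrom utils read.table head
NULL

# Convert a 0-based half-open interval data.frame to GRanges (1-based closed).
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# GRanges for 0-based point positions.
.pos_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr with the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic, platform-independent string hash mapped to [0, 1).
# Used to assign features to train/validation splits independent of row
# order (multiplicative hash over bytes, modulus 2^31 - 1).
.id_hash <- function(ids, seed = 0L) {
  m <- 2147483647
  vapply(as.character(ids), function(s) {
    h <- (as.numeric(seed) %% m) + 1
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% m
    # one extra mixing round so short ids spread out
    h <- (h * 2654435761) %% m
    h / m
  }, numeric(1), USE.NAMES = FALSE)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    .stopf("%s is missing required column(s): %s", what,
           paste(miss, collapse = ", "))
  }
}
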