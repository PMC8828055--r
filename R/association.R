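# Association analyses: GC-sorted binning, between-genotype change
# statistics, correlation matrices, PCA, and group comparisons.

#' GC-sorted binned association
#'
#' Sorts features by GC content (stable; ties broken by feature id), splits
#' the sorted order into consecutive blocks of `bin_size` features (only
#' the final block may be smaller), and returns per-block means of two
#' variables. Averaging blocks of 100 TEs reduces the variability of
#' per-element enrichments before plotting one variable against another.
#'
#' @param gc Per-feature GC content.
#' @param values_x,values_y Per-feature values to average per block.
#' @param ids Feature ids (tie-break and bookkeeping).
#' @param bin_size Features per block (default 100).
#' @return A `data.frame`: `bin`, `n`, `mean_gc`, `mean_x`, `mean_y`, plus
#'   a list-column `ids` of the member ids.
#' @export
gc_sorted_binning <- function(gc, values_x, values_y, ids = NULL,
                              bin_size = 100) {
  n <- length(gc)
  stopifnot(length(values_x) == n, length(values_y) == n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n < bin_size) {
    warning("fewer features than bin_size; returning a single bin")
  }
  o <- order(gc, ids)
  bin <- ceiling(seq_len(n) / bin_size)
  dt <- data.table::data.table(bin = bin, gc = gc[o], x = values_x[o],
                               y = values_y[o], id = ids[o])
  agg <- dt[, .(n = .N, mean_gc = mean(gc), mean_x = mean(x),
                mean_y = mean(y), ids = list(id)), by = bin]
  as.data.frame(agg)
}

#' Per-feature change and class-level fold change between genotypes
#'
#' @param values_a,values_b Per-feature values in the reference and the
#'   comparison genotype; either both named by feature id or positionally
#'   matched.
#' @param classes Optional per-feature class labels; fold changes are
#'   reported per class (and overall as class `"all"`).
#' @return A list with `delta` (data.frame `id`, `a`, `b`, `delta = b - a`)
#'   and `fold` (data.frame `class`, `mean_a`, `mean_b`, `fold`); `fold` is
#'   `NA` (flagged) where `mean_a` is 0.
#' @export
genotype_change <- function(values_a, values_b, classes = NULL) {
  if (!is.null(names(values_a)) && !is.null(names(values_b))) {
    if (!setequal(names(values_a), names(values_b))) {
      .stopf("feature ids of the two genotypes do not match")
    }
    values_b <- values_b[names(values_a)]
    ids <- names(values_a)
  } else {
    if (length(values_a) != length(values_b)) {
      .stopf("value vectors have different lengths and no ids to match on")
    }
    ids <- as.character(seq_along(values_a))
  }
  delta <- data.frame(id = ids, a = unname(values_a), b = unname(values_b),
                      delta = unname(values_b - values_a),
                      stringsAsFactors = FALSE)
  if (is.null(classes)) classes <- rep("all", length(ids))
  if (!is.null(names(classes))) classes <- classes[ids]
  cl <- unique(classes)
  fold <- data.frame(
    class = cl,
    mean_a = vapply(cl, function(k) mean(values_a[classes == k]), 0),
    mean_b = vapply(cl, function(k) mean(values_b[classes == k]), 0),
    stringsAsFactors = FALSE
  )
  fold$fold <- ifelse(fold$mean_a == 0, NA_real_, fold$mean_b / fold$mean_a)
  rownames(fold) <- NULL
  list(delta = delta, fold = fold)
}

#' Pairwise Pearson correlation matrix
#'
#' @param m Numeric matrix or data.frame (features x variables), at least
#'   3 rows. Constant columns are excluded and reported via attribute
#'   `"constant_columns"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(m) {
  m <- as.matrix(m[, vapply(as.data.frame(m), is.numeric, logical(1)),
                   drop = FALSE])
  if (nrow(m) < 3) .stopf("need at least 3 rows for a correlation matrix")
  const <- apply(m, 2, function(x) var(x) == 0 || any(is.na(x)))
  res <- cor(m[, !const, drop = FALSE])
  diag(res) <- 1
  attr(res, "constant_columns") <- colnames(m)[const]
  res
}

#' Principal component analysis of a feature matrix
#'
#' Columns are z-scored before decomposition (the variables mix log-ratios,
#' proportions and densities on different scales). Constant columns are
#' dropped first.
#'
#' @param m Numeric matrix or data.frame (features x variables).
#' @param n_components Number of components to return (default: all).
#' @return A list: `scores` (features x components), `loadings`
#'   (orthonormal, variables x components), `explained_variance`
#'   (non-increasing), `explained_fraction`.
#' @export
pca_features <- function(m, n_components = NULL) {
  m <- as.matrix(m[, vapply(as.data.frame(m), is.numeric, logical(1)),
                   drop = FALSE])
  const <- apply(m, 2, function(x) var(x) == 0)
  m <- m[, !const, drop = FALSE]
  if (is.null(n_components)) n_components <- ncol(m)
  if (n_components > ncol(m)) {
    .stopf("n_components (%d) exceeds the number of usable columns (%d)",
           n_components, ncol(m))
  }
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  k <- seq_len(n_components)
  list(scores = p$x[, k, drop = FALSE],
       loadings = p$rotation[, k, drop = FALSE],
       explained_variance = p$sdev[k]^2,
       explained_fraction = p$sdev[k]^2 / sum(p$sdev^2))
}

#' Pairwise group comparisons
#'
#' Two-sided rank-sum (Mann-Whitney U / Wilcoxon) test for every pair of
#' groups, with Benjamini-Hochberg-adjusted p-values alongside the raw
#' ones. The reported `statistic` is the U of the first group of the pair
#' (number of (first, second) pairs where the first value wins).
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 groups, each with >= 2
#'   members).
#' @param test `"ranksum"` (default) or `"t"` (Welch).
#' @return A `data.frame`: `group_a`, `group_b`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
group_compare <- function(values, groups, test = c("ranksum", "t")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) .stopf("need at least 2 groups")
  if (any(tab < 2)) {
    .stopf("group(s) with fewer than 2 members: %s",
           paste(names(tab)[tab < 2], collapse = ", "))
  }
  gs <- names(tab)
  pairs <- utils::combn(gs, 2)
  res <- apply(pairs, 2, function(p) {
    x <- values[groups == p[1]]
    y <- values[groups == p[2]]
    if (test == "ranksum") {
      w <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
      c(stat = unname(w$statistic), p = w$p.value)
    } else {
      w <- t.test(x, y)
      c(stat = unname(w$statistic), p = w$p.value)
    }
  })
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    statistic = res["stat", ], p_value = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
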