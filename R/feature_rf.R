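# Feature matrix assembly and tree-ensemble classification: which
# chromatin features discriminate CMT from DRM TEs, and how well can the
# class be predicted on held-out TEs.

#' Assemble a per-TE feature matrix
#'
#' One row per feature; columns combine methylation levels and densities
#' (from [summarize_methylation()]), arbitrary per-feature tracks (ChIP
#' log2 ratios, sRNA rpkm, ...), GC content, and per-(sub)context cytosine
#' sequence densities (sites per bp, both strands: CG, CCG, CWG, CHG, CHH,
#' CWA, nonCWA) computed from the genome. Rows with any undefined value
#' are dropped and reported via the `"dropped"` attribute.
#'
#' @param features A [feature_intervals()] data.frame.
#' @param meth_summary Output of [summarize_methylation()] for `features`
#'   (matched by `id`), or `NULL` to skip methylation columns.
#' @param tracks Named list of per-feature numeric vectors, each either
#'   named by feature id or positionally matched to `features`.
#' @param genome Named character vector of chromosome sequences, or `NULL`
#'   to skip sequence-composition columns.
#' @param labels Optional per-feature class labels (named by id or
#'   positional); stored in a `label` column. Rows with `NA` labels are
#'   kept (prediction targets) unless `drop_unlabeled = TRUE`.
#' @param drop_unlabeled Drop rows with `NA` label (default `FALSE`).
#' @return A `data.frame` keyed by `id` with numeric predictor columns (and
#'   optional `label`); attribute `"dropped"` lists ids removed for
#'   undefined values.
#' @export
build_feature_matrix <- function(features, meth_summary = NULL,
                                 tracks = list(), genome = NULL,
                                 labels = NULL, drop_unlabeled = FALSE) {
  out <- data.frame(id = features$id, stringsAsFactors = FALSE)
  len <- features$end - features$start
  if (!is.null(meth_summary)) {
    keep <- c("id", grep("^(m|d)_", names(meth_summary), value = TRUE))
    ms <- meth_summary[, keep, drop = FALSE]
    if (!all(out$id %in% ms$id)) {
      .stopf("meth_summary is missing feature id(s): %s",
             paste(utils::head(setdiff(out$id, ms$id), 5), collapse = ", "))
    }
    out <- merge(out, ms, by = "id", sort = FALSE)
  }
  align_track <- function(v, nm) {
    if (!is.null(names(v))) {
      miss <- setdiff(out$id, names(v))
      if (length(miss) > 0) {
        .stopf("track '%s' is missing feature id(s): %s", nm,
               paste(utils::head(miss, 5), collapse = ", "))
      }
      unname(v[out$id])
    } else {
      if (length(v) != nrow(features)) {
        .stopf("track '%s' has %d values for %d features", nm, length(v),
               nrow(features))
      }
      v[match(out$id, features$id)]
    }
  }
  for (nm in names(tracks)) out[[nm]] <- align_track(tracks[[nm]], nm)
  if (!is.null(genome)) {
    comp <- sequence_composition(features, genome)
    out <- merge(out, comp, by = "id", sort = FALSE)
  }
  if (!is.null(labels)) {
    out$label <- as.character(align_track(labels, "labels"))
    if (drop_unlabeled) out <- out[!is.na(out$label), , drop = FALSE]
  }
  num <- vapply(out, is.numeric, logical(1))
  complete <- rowSums(is.na(out[, num, drop = FALSE])) == 0
  dropped <- out$id[!complete]
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' GC content and context-site densities per feature
#'
#' @param features A [feature_intervals()] data.frame.
#' @param genome Named character vector of chromosome sequences.
#' @return A `data.frame`: `id`, `gc` (fraction of G/C bases), and
#'   `dens_<ctx>` columns (sites per bp, both strands) for CG, CCG, CWG,
#'   CHG, CHH, CWA, nonCWA.
#' @export
sequence_composition <- function(features, genome) {
  sites <- cytosine_sites(genome)
  len <- features$end - features$start
  hits <- GenomicRanges::findOverlaps(.pos_granges(sites$chrom, sites$pos),
                                      .as_granges(features))
  dt <- data.table::data.table(
    fi = S4Vectors::subjectHits(hits),
    context = sites$context[S4Vectors::queryHits(hits)],
    subcontext = sites$subcontext[S4Vectors::queryHits(hits)]
  )
  out <- data.frame(id = features$id, gc = NA_real_,
                    stringsAsFactors = FALSE)
  for (ctx in c("CG", "CHG", "CHH")) {
    cnt <- dt[context == ctx, .N, by = fi]
    v <- numeric(nrow(features)); v[cnt$fi] <- cnt$N
    out[[paste0("dens_", ctx)]] <- v / len
  }
  for (sub in c("CCG", "CWG", "CWA", "nonCWA")) {
    cnt <- dt[subcontext == sub, .N, by = fi]
    v <- numeric(nrow(features)); v[cnt$fi] <- cnt$N
    out[[paste0("dens_", sub)]] <- v / len
  }
  for (i in seq_len(nrow(features))) {
    s <- substring(genome[[features$chrom[i]]], features$start[i] + 1,
                   features$end[i])
    bases <- strsplit(s, "", fixed = TRUE)[[1]]
    out$gc[i] <- mean(bases %in% c("G", "C"))
  }
  out
}

# Stratified, row-order-independent train/validation split: features are
# assigned by a seeded hash of their ids, within each class.
.split_train <- function(ids, labels, split_fraction, seed) {
  h <- .id_hash(ids, seed)
  train <- logical(length(ids))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    k <- max(1L, round(split_fraction * length(i)))
    train[i[order(h[i])][seq_len(k)]] <- TRUE
  }
  train
}

#' Train and evaluate a random-forest TE classifier
#'
#' Splits features into training and validation sets (stratified by class;
#' assignment decided by a seeded hash of feature ids so the result is
#' independent of row order), fits a random forest (bagged trees with
#' per-tree bootstrap and sqrt(p) feature subsampling) on the training rows
#' using only the requested predictors, and reports the held-out
#' validation error rate alongside the out-of-bag estimate.
#'
#' @param m Feature matrix from [build_feature_matrix()] with a `label`
#'   column (two or more classes).
#' @param predictors Character vector of predictor column names; `NULL`
#'   uses every numeric column.
#' @param label_col Name of the label column (default `"label"`).
#' @param split_fraction Fraction of features used for training
#'   (default 0.5).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed controlling both the split and the forest.
#' @return A list of class `classifier_report`: `error_rate` (held-out),
#'   `oob_error`, `predictions` (id, observed, predicted), `n_train`,
#'   `n_validate`, `predictors`, `n_trees`, `seed`.
#' @export
train_eval_classifier <- function(m, predictors = NULL, label_col = "label",
                                  split_fraction = 0.5, n_trees = 500,
                                  seed = 1) {
  if (!label_col %in% names(m)) .stopf("no '%s' column in matrix", label_col)
  m <- m[!is.na(m[[label_col]]), , drop = FALSE]
  if (is.null(predictors)) {
    predictors <- names(m)[vapply(m, is.numeric, logical(1))]
  }
  miss <- setdiff(predictors, names(m))
  if (length(miss) > 0) {
    .stopf("predictor(s) not in matrix: %s", paste(miss, collapse = ", "))
  }
  # canonical row order so the fit does not depend on input row order
  m <- m[order(m$id), , drop = FALSE]
  y <- factor(m[[label_col]])
  train <- .split_train(m$id, as.character(y), split_fraction, seed)
  if (length(unique(y[train])) < 2) {
    .stopf("training split contains a single class")
  }
  x <- m[, predictors, drop = FALSE]
  fit <- .with_seed(seed, randomForest::randomForest(
    x = x[train, , drop = FALSE], y = droplevels(y[train]),
    ntree = n_trees))
  pred <- predict(fit, x[!train, , drop = FALSE])
  obs <- as.character(y[!train])
  err <- mean(as.character(pred) != obs)
  structure(list(
    error_rate = err,
    oob_error = unname(fit$err.rate[n_trees, "OOB"]),
    predictions = data.frame(id = m$id[!train], observed = obs,
                             predicted = as.character(pred),
                             stringsAsFactors = FALSE),
    n_train = sum(train), n_validate = sum(!train),
    predictors = predictors, n_trees = n_trees, seed = seed
  ), class = "classifier_report")
}

#' Random-forest variable importance
#'
#' Fits a forest on all labelled rows and reports, per predictor, the
#' permutation-based mean decrease in accuracy and the mean decrease in
#' node impurity (Gini), with ranks on both measures.
#'
#' @inheritParams train_eval_classifier
#' @return A `data.frame` sorted by accuracy importance: `variable`,
#'   `mean_decrease_accuracy`, `mean_decrease_gini`, `rank_accuracy`,
#'   `rank_gini`.
#' @export
variable_importance <- function(m, predictors = NULL, label_col = "label",
                                n_trees = 500, seed = 1) {
  if (!label_col %in% names(m)) .stopf("no '%s' column in matrix", label_col)
  m <- m[!is.na(m[[label_col]]), , drop = FALSE]
  if (is.null(predictors)) {
    predictors <- names(m)[vapply(m, is.numeric, logical(1))]
  }
  miss <- setdiff(predictors, names(m))
  if (length(miss) > 0) {
    .stopf("predictor(s) not in matrix: %s", paste(miss, collapse = ", "))
  }
  m <- m[order(m$id), , drop = FALSE]
  y <- factor(m[[label_col]])
  fit <- .with_seed(seed, randomForest::randomForest(
    x = m[, predictors, drop = FALSE], y = y, ntree = n_trees,
    importance = TRUE))
  imp <- randomForest::importance(fit)
  out <- data.frame(
    variable = rownames(imp),
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"]),
    stringsAsFactors = FALSE
  )
  out$rank_accuracy <- rank(-out$mean_decrease_accuracy, ties.method = "min")
  out$rank_gini <- rank(-out$mean_decrease_gini, ties.method = "min")
  out[order(out$rank_accuracy), ]
}
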