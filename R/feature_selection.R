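# Importance scoring (F-score, gradient boosting, random forest, MRMD),
# top-n pre-filtering and AUC-driven sequential forward selection.

#' Importance ranking container
#'
#' @param method one of FSCORE, GBT, RF, MRMD.
#' @param scores numeric per-feature scores (higher = better).
#' @return object of class `importance_ranking` with `order` (feature indices
#'   sorted by score descending, ties broken by original column index) and
#'   `scores`.
#' @export
importance_ranking <- function(method, scores) {
  ord <- order(-scores, seq_along(scores))   # stable: ties by column index
  structure(list(method = method, order = ord, scores = scores),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("<importance_ranking ", x$method, ": ", length(x$order),
      " features, top index ", x$order[1], ">\n", sep = "")
  invisible(x)
}

.check_two_classes <- function(y) {
  if (length(unique(y)) != 2L) stop("two classes required")
}

#' Two-class F-score importance
#'
#' Per feature: `((mean+ - mean)^2 + (mean- - mean)^2) / (var+ + var-)` with
#' class-wise sample variances; features with zero variance in both classes
#' score 0.
#'
#' @param X numeric matrix (samples x features).
#' @param y 0/1 labels.
#' @return an `importance_ranking`.
#' @export
fscore_importance <- function(X, y) {
  X <- as.matrix(X)
  .check_two_classes(y)
  pos <- y == 1
  mu  <- colMeans(X)
  mup <- colMeans(X[pos, , drop = FALSE])
  mun <- colMeans(X[!pos, , drop = FALSE])
  vp  <- apply(X[pos, , drop = FALSE], 2L, stats::var)
  vn  <- apply(X[!pos, , drop = FALSE], 2L, stats::var)
  num <- (mup - mu)^2 + (mun - mu)^2
  den <- vp + vn
  # zero within-class variance: constant feature scores 0, a feature that
  # still differs between classes separates perfectly and ranks first
  scores <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  importance_ranking("FSCORE", unname(scores))
}

#' Gradient-boosted-tree importance
#'
#' Gain importance from a seeded single-threaded gradient-boosted tree
#' ensemble; features never used in a split score 0.
#'
#' @param X numeric matrix.
#' @param y 0/1 labels.
#' @param seed integer seed.
#' @param nrounds boosting rounds.
#' @param max_depth tree depth.
#' @return an `importance_ranking`.
#' @export
gbt_importance <- function(X, y, seed = 1L, nrounds = 50L, max_depth = 6L) {
  X <- as.matrix(X)
  .check_two_classes(y)
  nms <- paste0("f", seq_len(ncol(X)))
  colnames(X) <- nms
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1)
  fit <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = 0.3, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  ))
  imp <- xgboost::xgb.importance(model = fit)
  scores <- numeric(ncol(X))
  if (nrow(imp) > 0L) scores[match(imp$Feature, nms)] <- imp$Gain
  importance_ranking("GBT", scores)
}

#' Random-forest importance
#'
#' Impurity-decrease (Gini) importance from a seeded single-threaded random
#' forest.
#'
#' @param X numeric matrix.
#' @param y 0/1 labels.
#' @param seed integer seed.
#' @param num_trees number of trees.
#' @return an `importance_ranking`.
#' @export
rf_importance <- function(X, y, seed = 1L, num_trees = 300L) {
  X <- as.matrix(X)
  .check_two_classes(y)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(x = as.data.frame(X), y = factor(y),
                        importance = "impurity", num.trees = num_trees,
                        seed = seed, num.threads = 1L)
  importance_ranking("RF", as.numeric(fit$variable.importance))
}

#' Max-Relevance-Max-Distance (MRMD) importance
#'
#' Per feature, on z-scored columns:
#' `score = w_rel * |Pearson(f, labels)| + w_dist * mean Euclidean distance`
#' from the feature to every other feature. Zero-variance features get
#' relevance 0. Redundant (near-duplicate) features are penalized through the
#' distance term.
#'
#' @param X numeric matrix.
#' @param y 0/1 labels.
#' @param w_rel,w_dist term weights (equal by default).
#' @return an `importance_ranking`.
#' @export
mrmd_importance <- function(X, y, w_rel = 1, w_dist = 1) {
  X <- as.matrix(X)
  .check_two_classes(y)
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  rel <- abs(suppressWarnings(stats::cor(X, as.numeric(y))))[, 1]
  rel[is.na(rel)] <- 0
  D <- as.matrix(stats::dist(t(Z)))
  mdist <- if (ncol(X) > 1L) rowSums(D) / (ncol(X) - 1L) else rep(0, ncol(X))
  importance_ranking("MRMD", unname(w_rel * rel + w_dist * mdist))
}

#' Keep the n best-ranked columns of a block
#'
#' Preserves the original relative column order of the kept features. If the
#' block has fewer than `n` columns, all are kept with a warning.
#'
#' @param block a `feature_block`.
#' @param ranking an `importance_ranking` over the block's columns.
#' @param n number of features to keep (default 250).
#' @return a `feature_block` with at most `n` columns.
#' @export
prefilter_top <- function(block, ranking, n = 250L) {
  width <- ncol(block$values)
  if (width < n) {
    warning("block ", block$block_name, " has ", width, " < ", n,
            " features; keeping all")
    return(block)
  }
  keep <- sort(ranking$order[seq_len(n)])
  feature_block(block$block_name, block$feature_names[keep],
                block$values[, keep, drop = FALSE])
}

#' Sequential forward selection (SFS)
#'
#' Features are added one by one in ranking order; at each step the
#' cross-validated classifier metrics are recorded, and the selected subset
#' is the prefix maximizing AUC (first maximizer on ties).
#'
#' @param X numeric matrix (samples x features).
#' @param y 0/1 labels.
#' @param ranking an `importance_ranking` covering all columns of `X`.
#' @param evaluator `function(Xsub, y) -> named vector with acc, sn, sp, mcc,
#'   auc`; default: stratified 5-fold CV of the RBF-SVM.
#' @param max_features evaluate at most this many steps (default: all).
#' @param cv_folds,seed fold setup for the default evaluator.
#' @return object of class `sfs_result` with `curve` (data.frame of per-step
#'   metrics), `best_subset` (original column indices, in ranking order) and
#'   `best_auc`.
#' @export
sfs <- function(X, y, ranking, evaluator = NULL, max_features = NULL,
                cv_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (length(ranking$order) != ncol(X)) stop("ranking must cover all columns")
  if (is.null(evaluator)) {
    folds <- make_cv_folds(y, cv_folds, seed)
    evaluator <- function(Xsub, y) svm_cv_metrics(Xsub, y, folds)
  }
  steps <- min(ncol(X), if (is.null(max_features)) ncol(X) else max_features)
  curve <- data.frame(step = seq_len(steps), acc = NA_real_, sn = NA_real_,
                      sp = NA_real_, mcc = NA_real_, auc = NA_real_)
  for (s in seq_len(steps)) {
    m <- tryCatch(evaluator(X[, ranking$order[seq_len(s)], drop = FALSE], y),
                  error = function(e) stop("SFS evaluator failed at step ", s,
                                           ": ", conditionMessage(e)))
    curve[s, c("acc", "sn", "sp", "mcc", "auc")] <-
      m[c("acc", "sn", "sp", "mcc", "auc")]
  }
  best_step <- which.max(curve$auc)           # first maximizer on ties
  structure(list(curve = curve,
                 best_subset = ranking$order[seq_len(best_step)],
                 best_auc = curve$auc[best_step]),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat("<sfs_result: ", nrow(x$curve), " steps, best subset ",
      length(x$best_subset), " features, AUC ", round(x$best_auc, 4), ">\n",
      sep = "")
  invisible(x)
}

#' Write an SFS curve as TSV
#'
#' @param result an `sfs_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sfs_tsv <- function(result, path) {
  utils::write.table(result$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
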