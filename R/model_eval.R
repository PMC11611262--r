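# Final classifier and the five evaluation metrics (ACC, SN, SP, MCC, AUC).
# Scores are logistic-transformed SVM decision values: monotone in the margin
# and deterministic (libsvm's Platt probability fitting uses an unseedable
# RNG, so it is deliberately avoided).

#' Stratified cross-validation fold assignment
#'
#' @param y 0/1 label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), one per sample, with both
#'   classes spread evenly across folds.
#' @export
make_cv_folds <- function(y, k = 5L, seed = 1L) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  if (any(table(folds, y) == 0L)) stop("a fold lost one class; use fewer folds")
  folds
}

# Fit one RBF-SVM and return decision values for newdata, oriented so that
# larger values favor class 1 (libsvm reports the orientation in the
# decision-value column name, e.g. "1/0": positive margin -> class "1").
.svm_scores <- function(Xtr, ytr, Xte, cost, gamma) {
  fit <- e1071::svm(Xtr, factor(ytr, levels = c(0, 1)), kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  dvm <- attr(stats::predict(fit, Xte, decision.values = TRUE),
              "decision.values")
  dv <- as.numeric(dvm)
  if (sub("/.*", "", colnames(dvm)[1]) == "0") dv <- -dv
  dv
}

#' Out-of-fold SVM scores under cross-validation
#'
#' @param X numeric matrix (samples x features).
#' @param y 0/1 labels.
#' @param folds fold ids from [make_cv_folds()].
#' @param cost,gamma RBF-SVM hyperparameters (`gamma = NULL` uses `1/ncol(X)`).
#' @return numeric vector of scores in (0, 1), one per sample.
#' @export
svm_cv_scores <- function(X, y, folds, cost = 1, gamma = NULL) {
  X <- as.matrix(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  scores <- numeric(length(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    scores[te] <- .svm_scores(X[!te, , drop = FALSE], y[!te],
                              X[te, , drop = FALSE], cost, gamma)
  }
  stats::plogis(scores)
}

#' Cross-validated metrics of the RBF-SVM
#'
#' Pools out-of-fold scores and computes the five evaluation metrics.
#'
#' @inheritParams svm_cv_scores
#' @param threshold decision threshold on the score.
#' @return named numeric vector `acc, sn, sp, mcc, auc`.
#' @export
svm_cv_metrics <- function(X, y, folds, cost = 1, gamma = NULL, threshold = 0.5) {
  s <- svm_cv_scores(X, y, folds, cost, gamma)
  rep <- eval_report(s, y, threshold)
  c(acc = rep$acc, sn = rep$sn, sp = rep$sp, mcc = rep$mcc, auc = rep$auc)
}

#' Cross-validated AUC of the RBF-SVM
#'
#' The default fitness used by the genetic algorithm and the sequential
#' forward selection.
#'
#' @inheritParams svm_cv_scores
#' @return AUC in `[0, 1]`.
#' @export
svm_cv_auc <- function(X, y, folds, cost = 1, gamma = NULL) {
  roc_auc(svm_cv_scores(X, y, folds, cost, gamma), y)$auc
}

#' Train the final RBF-SVM with a small hyperparameter grid search
#'
#' Selects `cost` and `gamma` by cross-validated AUC, then refits on all
#' samples.
#'
#' @param X numeric matrix (samples x features).
#' @param y 0/1 labels.
#' @param cost_grid,gamma_grid candidate values (`gamma_grid = NULL` uses
#'   multiples of `1/ncol(X)`).
#' @param cv_folds folds for the selection.
#' @param seed integer seed (fold assignment).
#' @return object of class `phospho_svm`.
#' @export
train_classifier <- function(X, y, cost_grid = c(1, 4, 16), gamma_grid = NULL,
                             cv_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (length(unique(y)) != 2L) stop("two classes required")
  if (is.null(gamma_grid)) gamma_grid <- c(0.25, 1, 4) / ncol(X)
  folds <- make_cv_folds(y, cv_folds, seed)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    svm_cv_auc(X, y, folds, grid$cost[i], grid$gamma[i])
  }, numeric(1))
  best <- grid[order(-grid$auc, grid$cost, grid$gamma)[1], ]
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                    cost = best$cost, gamma = best$gamma, scale = FALSE)
  dvm <- attr(stats::predict(fit, X[1, , drop = FALSE],
                             decision.values = TRUE), "decision.values")
  structure(list(fit = fit, cost = best$cost, gamma = best$gamma,
                 cv_auc = best$auc, grid = grid,
                 flip = sub("/.*", "", colnames(dvm)[1]) == "0",
                 feature_names = colnames(X)),
            class = "phospho_svm")
}

#' @export
print.phospho_svm <- function(x, ...) {
  cat("<phospho_svm: RBF-SVM on ", length(x$feature_names), " features, cost ",
      x$cost, ", gamma ", signif(x$gamma, 3), ", CV AUC ",
      round(x$cv_auc, 4), ">\n", sep = "")
  invisible(x)
}

#' Predict phosphorylation scores
#'
#' @param object a `phospho_svm`.
#' @param newdata matrix with the model's feature columns.
#' @param ... unused.
#' @return numeric score in (0, 1) per row (logistic of the SVM margin).
#' @export
predict.phospho_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  dv <- as.numeric(attr(stats::predict(object$fit, newdata,
                                       decision.values = TRUE),
                        "decision.values"))
  if (object$flip) dv <- -dv
  stats::plogis(dv)
}

#' Confusion counts at a score threshold
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold predicted positive iff `score >= threshold`.
#' @return list with integer fields `tp, fp, tn, fn`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- scores >= threshold
  pos <- labels == 1
  list(tp = sum(pred & pos), fp = sum(pred & !pos),
       tn = sum(!pred & !pos), fn = sum(!pred & pos))
}

#' Threshold metrics from confusion counts
#'
#' `ACC = (TP+TN)/n`, `SN = TP/(TP+FN)`, `SP = TN/(TN+FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((FP+TP)(FN+TP)(FP+TN)(FN+TN))`. A zero SN/SP
#' denominator yields `NA`; a zero MCC denominator yields 0 with a warning.
#'
#' @param counts list with `tp, fp, tn, fn` (see [confusion()]).
#' @return list with `acc, sn, sp, mcc`.
#' @export
eval_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  stopifnot(n > 0)
  acc <- (tp + tn) / n
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den2 <- as.numeric(fp + tp) * (fn + tp) * (fp + tn) * (fn + tn)
  if (den2 == 0) {
    warning("MCC denominator is zero; returning 0")
    mcc <- 0
  } else {
    mcc <- (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den2)
  }
  list(acc = acc, sn = sn, sp = sp, mcc = mcc)
}

#' ROC curve and area under it
#'
#' Sweeps all score thresholds; `TPR = TP/(TP+FN)`, `FPR = FP/(TN+FP)`; the
#' area is the trapezoidal sum (equivalent to the normalized Mann-Whitney U
#' with ties counted half).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `auc` and `roc`, a data.frame of (fpr, tpr) points.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L) stop("both classes required for ROC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single ROC points
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(p)[last_of_tie] / P)
  fpr <- c(0, cumsum(!p)[last_of_tie] / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Full evaluation report
#'
#' Confusion-based metrics at `threshold` plus the ROC/AUC and the
#' sensitivity-specificity gap `|SN - SP|` in percent (the prediction-bias
#' indicator).
#'
#' @param scores numeric scores in (0, 1).
#' @param labels 0/1 labels.
#' @param threshold decision threshold.
#' @return list of class `eval_report` with fields `acc, sn, sp, mcc, auc,
#'   sn_sp_gap, counts, roc, threshold`.
#' @export
eval_report <- function(scores, labels, threshold = 0.5) {
  counts <- confusion(scores, labels, threshold)
  m <- eval_metrics(counts)
  r <- roc_auc(scores, labels)
  structure(c(m, list(auc = r$auc, sn_sp_gap = abs(m$sn - m$sp) * 100,
                      counts = counts, roc = r$roc, threshold = threshold)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: ACC %.4f  SN %.4f  SP %.4f  |SN-SP|%% %.2f  MCC %.4f  AUC %.4f>\n",
    x$acc, x$sn, x$sp, x$sn_sp_gap, x$mcc, x$auc))
  invisible(x)
}
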