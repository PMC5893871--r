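#' Stratified k-fold assignment
#'
#' Partitions samples into k folds so that per-class counts across folds
#' differ by at most one; classes with fewer than k samples are spread as
#' evenly as possible. Reproducible for a fixed seed.
#'
#' @param labels vector of class labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), one per sample.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    # rotate the starting fold between classes so fold sizes stay balanced
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Accuracy, sensitivity and specificity from one-vs-rest confusion counts
#'
#' accuracy = (TP + TN) / (TP + FP + TN + FN); sensitivity = TP / (TP + FN);
#' specificity = TN / (TN + FP). A zero denominator yields \code{NA} for that
#' metric rather than an error.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return named numeric vector \code{c(accuracy, sensitivity, specificity)}.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  tot <- tp + tn + fp + fn
  if (tot == 0) stop("no samples")
  c(accuracy = (tp + tn) / tot,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' ROC curve and AUC for a binary scoring
#'
#' AUC is computed as the pairwise concordance probability (Mann-Whitney
#' statistic): the probability that a random positive outscores a random
#' negative, ties counting one half. The ROC points returned integrate to the
#' same value by the trapezoidal rule.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return list with \code{auc} and a data.frame \code{curve} of (fpr, tpr)
#'   points at every threshold.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord]); fp <- cumsum(!y[ord])
  # collapse tied thresholds
  last <- c(diff(scores[ord]) != 0, TRUE)
  curve <- data.frame(fpr = c(0, fp[last] / nneg),
                      tpr = c(0, tp[last] / npos))
  list(auc = auc, curve = curve)
}

# mode of randomForest probability scoring for one fold
rf_fold <- function(x_train, y_train, x_test, n_trees, seed) {
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x_train, y_train, ntree = n_trees)
  list(pred = stats::predict(fit, x_test),
       prob = stats::predict(fit, x_test, type = "prob"))
}

#' Cross-validated random-forest evaluation of a feature table
#'
#' Stratified k-fold cross-validation of a random forest (default 100 trees)
#' on the z-scored texture features. Per fold and per class (one-vs-rest),
#' accuracy, sensitivity and specificity are computed from the predicted
#' labels and AUC from the out-of-fold class-probability scores; the
#' aggregate is the mean and SD over folds of the macro-average across
#' classes. The plain multiclass accuracy (fraction of correctly labeled
#' test samples) is reported alongside. \code{features} selects a subset of
#' feature columns (e.g. one octant's three quantifiers) to reproduce the
#' per-band experiment grid.
#'
#' @param table a z-scored \code{feature_table}.
#' @param features character vector of feature column names (default: all).
#' @param k folds (default 5).
#' @param n_trees random-forest size (default 100).
#' @param seed integer seed controlling folds and forests.
#' @return object of class \code{cv_report}.
#' @export
train_eval_cv <- function(table, features = NULL, k = 5L, n_trees = 100L,
                          seed = 1L) {
  all_feats <- setdiff(names(table), c("sample_id", "label"))
  if (is.null(features)) features <- all_feats
  if (length(features) == 0) stop("empty feature subset")
  missing <- setdiff(features, all_feats)
  if (length(missing) > 0)
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  y <- factor(table$label)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  x <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  fold <- stratified_kfold(as.character(y), k = k, seed = seed)
  classes <- levels(y)
  per_fold <- vector("list", k)
  fold_auc <- matrix(NA_real_, k, length(classes),
                     dimnames = list(NULL, classes))
  fold_metrics <- matrix(NA_real_, k, 4,
                         dimnames = list(NULL, c("accuracy", "sensitivity",
                                                 "specificity",
                                                 "multiclass_accuracy")))
  for (f in seq_len(k)) {
    te <- fold == f; tr <- !te
    res <- rf_fold(x[tr, , drop = FALSE], droplevels(y[tr]),
                   x[te, , drop = FALSE], n_trees, seed * 1000L + f)
    pred <- factor(as.character(res$pred), levels = classes)
    truth <- y[te]
    per_class <- sapply(classes, function(cl) {
      tp <- sum(pred == cl & truth == cl)
      tn <- sum(pred != cl & truth != cl)
      fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl)
      confusion_metrics(tp, tn, fp, fn)
    })
    fold_metrics[f, 1:3] <- rowMeans(per_class, na.rm = TRUE)
    fold_metrics[f, 4] <- mean(pred == truth)
    for (cl in classes) {
      if (cl %in% colnames(res$prob) && any(truth == cl) && any(truth != cl))
        fold_auc[f, cl] <- roc_auc(res$prob[, cl], truth == cl)$auc
    }
    per_fold[[f]] <- list(test_idx = which(te), predicted = pred,
                          truth = truth, prob = res$prob)
  }
  structure(list(
    fold_metrics = fold_metrics,
    fold_auc = fold_auc,
    mean = colMeans(fold_metrics, na.rm = TRUE),
    sd = apply(fold_metrics, 2, stats::sd, na.rm = TRUE),
    auc_mean = colMeans(fold_auc, na.rm = TRUE),
    auc_sd = apply(fold_auc, 2, stats::sd, na.rm = TRUE),
    folds = fold, per_fold = per_fold,
    features = features, k = k, n_trees = n_trees, seed = seed,
    classes = classes
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Random-forest cross-validation: %d folds, %d trees, %d features\n",
              x$k, x$n_trees, length(x$features)))
  m <- x$mean; s <- x$sd
  cat(sprintf("  macro accuracy    %.4f (+/- %.4f)\n", m["accuracy"], s["accuracy"]))
  cat(sprintf("  macro sensitivity %.4f (+/- %.4f)\n", m["sensitivity"], s["sensitivity"]))
  cat(sprintf("  macro specificity %.4f (+/- %.4f)\n", m["specificity"], s["specificity"]))
  cat(sprintf("  multiclass accuracy %.4f (+/- %.4f)\n",
              m["multiclass_accuracy"], s["multiclass_accuracy"]))
  cat("  per-class AUC (fold mean):",
      paste(sprintf("%s %.3f", names(x$auc_mean), x$auc_mean),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  cat("Per-fold metrics:\n"); print(round(object$fold_metrics, 4))
  cat("Per-fold one-vs-rest AUC:\n"); print(round(object$fold_auc, 4))
  invisible(object)
}

#' @export
plot.cv_report <- function(x, ...) {
  # pooled out-of-fold ROC curves, one per class
  classes <- x$classes
  cols <- grDevices::hcl.colors(length(classes), "Dark 3")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = "Out-of-fold one-vs-rest ROC")
  scores <- do.call(rbind, lapply(x$per_fold, function(f) f$prob))
  truth <- unlist(lapply(x$per_fold, function(f) as.character(f$truth)))
  for (i in seq_along(classes)) {
    r <- roc_auc(scores[, classes[i]], truth == classes[i])
    graphics::lines(r$curve$fpr, r$curve$tpr, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", classes, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Feature subsets of the octant/quantifier experiment grid
#'
#' Convenience constructor for the per-band (3 features each), per-quantifier
#' (8 features each) and combined (24 features) subsets evaluated in the
#' cross-validation experiments.
#'
#' @return named list of character vectors of feature names.
#' @export
feature_subsets <- function() {
  q <- c("variance", "entropy", "energy")
  oct <- octant_keys()
  subsets <- c(
    stats::setNames(lapply(oct, function(o) paste(q, o, sep = "_")), oct),
    stats::setNames(lapply(q, function(qq) paste(qq, oct, sep = "_")), q),
    list(combined = as.vector(outer(q, oct, paste, sep = "_")))
  )
  subsets
}
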