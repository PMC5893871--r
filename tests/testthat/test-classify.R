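test_that("stratified folds partition samples with balanced class counts", {
  labels <- rep(c("ST", "BH", "IN", "CA"), c(9, 10, 9, 11))
  f <- stratified_kfold(labels, k = 5, seed = 3)
  expect_length(f, 39)
  expect_setequal(unique(f), 1:5)
  sizes <- tabulate(f, 5)
  expect_true(all(sizes %in% 7:8))
  for (cl in unique(labels)) {
    per <- tabulate(f[labels == cl], 5)
    expect_lte(diff(range(per)), 1)
  }
  expect_identical(f, stratified_kfold(labels, k = 5, seed = 3))
  expect_false(identical(f, stratified_kfold(labels, k = 5, seed = 4)))
  expect_error(stratified_kfold(labels, k = 1), "k must be")
})

test_that("confusion metrics follow their closed-form definitions", {
  m <- confusion_metrics(tp = 8, tn = 27, fp = 2, fn = 3)
  expect_equal(unname(m), c(0.875, 8 / 11, 27 / 29))
  expect_equal(unname(confusion_metrics(10, 30, 0, 0)), c(1, 1, 1))
  expect_equal(unname(confusion_metrics(0, 30, 0, 5)["sensitivity"]), 0)
  expect_true(is.na(confusion_metrics(0, 30, 0, 0)["sensitivity"]))
  expect_error(confusion_metrics(-1, 0, 0, 2), "non-negative")
})

test_that("AUC equals the pairwise concordance probability", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  trapezoid <- function(curve) {
    o <- order(curve$fpr, curve$tpr)
    x <- curve$fpr[o]; y <- curve$tpr[o]
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), sample(c(1, 8), 1))  # force some ties sometimes
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, trapezoid(r$curve), tolerance = 1e-12)
    # brute-force concordance oracle
    pos <- scores[labels]; neg <- scores[!labels]
    conc <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, conc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- rnorm(40)
  labels <- runif(40) < 0.5
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("cross-validated evaluation is reproducible and validates subsets", {
  co <- generate_cohort(counts = c(ST = 4, BH = 4, IN = 4, CA = 4),
                        params = small_params(), seed = 21)
  z <- zscore_table(extract_features(co))
  cv1 <- train_eval_cv(z, k = 4, n_trees = 50, seed = 9)
  cv2 <- train_eval_cv(z, k = 4, n_trees = 50, seed = 9)
  expect_identical(cv1$mean, cv2$mean)
  expect_identical(cv1$fold_auc, cv2$fold_auc)

  # folds partition the cohort
  expect_setequal(unlist(lapply(cv1$per_fold, `[[`, "test_idx")),
                  seq_len(nrow(z)))
  expect_true(all(cv1$fold_metrics >= 0 & cv1$fold_metrics <= 1))
  # reported SDs recompute from the per-fold values
  expect_equal(unname(cv1$sd["accuracy"]),
               sd(cv1$fold_metrics[, "accuracy"]), tolerance = 1e-12)

  sub <- train_eval_cv(z, features = feature_subsets()$LLL, k = 4,
                       n_trees = 50, seed = 9)
  expect_length(sub$features, 3)
  expect_error(train_eval_cv(z, features = character(0)), "empty")
  expect_error(train_eval_cv(z, features = "nope"), "unknown feature")
})

test_that("the experiment grid exposes octant, quantifier and combined subsets", {
  fs <- feature_subsets()
  expect_length(fs, 12)
  expect_true(all(lengths(fs[1:8]) == 3))
  expect_true(all(lengths(fs[9:11]) == 8))
  expect_length(fs$combined, 24)
  expect_setequal(fs$combined, unique(unlist(fs[1:8])))
})
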