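# Metrics, confusion matrices, cross-validation, and the nonparametric
# feature-set comparison.

test_that("row normalization turns counts into class-conditional rates", {
  cm <- matrix(c(20, 2, 5, 23), 2, 2)  # rows: truth control, cancer
  norm <- confusion_normalized(cm)
  expect_equal(unclass(norm), matrix(c(0.8, 0.08, 0.2, 0.92), 2, 2),
               ignore_attr = TRUE)
  expect_equal(rowSums(norm), c(control = 1, cancer = 1), tolerance = 1e-12)
  # perfect classifier
  expect_equal(unclass(confusion_normalized(diag(c(10, 10)))), diag(2),
               ignore_attr = TRUE)
  # all-one-class predictions: a column of ones
  one_col <- confusion_normalized(matrix(c(0, 0, 10, 12), 2, 2))
  expect_equal(unname(one_col[, 2]), c(1, 1))
  # empty row flagged
  und <- confusion_normalized(matrix(c(0, 3, 0, 4), 2, 2))
  expect_true(all(is.na(und[1, ])))
  expect_identical(attr(und, "undefined_rows"), 1L)
})

test_that("accuracy, F1 and AUC match hand-computed values", {
  truth <- c("cancer", "cancer", "control", "control")
  pred <- c("cancer", "control", "control", "control")
  m <- classification_metrics(truth, pred, scores = c(0.9, 0.4, 0.3, 0.1))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$auc, 1)
  # perfect separation and full ties
  expect_equal(classification_metrics(
    c("cancer", "cancer", "control", "control"),
    rep("control", 4), c(0.9, 0.8, 0.1, 0.2))$auc, 1)
  expect_equal(classification_metrics(
    truth, pred, rep(0.5, 4))$auc, 0.5)
  # single-class truth: AUC undefined
  expect_true(is.na(classification_metrics(rep("cancer", 3),
                                           rep("cancer", 3),
                                           c(.1, .2, .3))$auc))
})

test_that("rank AUC equals brute-force Mann-Whitney over all pairs", {
  set.seed(1)
  for (rep in 1:10) {
    n <- sample(6:50, 1)
    truth <- sample(c("cancer", "control"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("cancer", "control")
    scores <- round(runif(n), 2)  # rounding forces ties
    pos <- scores[truth == "cancer"]; neg <- scores[truth == "control"]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(classification_metrics(truth, truth, scores)$auc, brute,
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  truth <- sample(c("cancer", "control"), 40, replace = TRUE)
  scores <- rnorm(40) + (truth == "cancer")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truth, c("control", "cancer")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(classification_metrics(truth, truth, scores)$auc, ref,
               tolerance = 1e-10)
})

test_that("stratified folds are balanced, disjoint, and seed-stable", {
  labels <- factor(rep(c("control", "cancer"), each = 25),
                   levels = c("control", "cancer"))
  folds <- stratified_folds(labels, 5, seed = 3)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(f, 10L)
    expect_identical(as.vector(table(labels[f])), c(5L, 5L))
  }
  expect_identical(sort(unlist(folds)), 1:50)
  expect_identical(stratified_folds(labels, 5, seed = 3), folds)
  expect_error(stratified_folds(factor(rep("cancer", 3)), 5), "too few")
})

test_that("cross-validation is deterministic and perfect on separable cohorts", {
  tensor <- separable_tensor(n_per_class = 10)
  cv <- cross_validate(tensor, tsf_pipeline(n_trees = 10), folds = 5,
                       seed = 4)
  expect_identical(cv$summary$mean[cv$summary$metric == "accuracy"], 1)
  expect_identical(cv$summary$sd[cv$summary$metric == "accuracy"], 0)
  cv2 <- cross_validate(tensor, tsf_pipeline(n_trees = 10), folds = 5,
                        seed = 4)
  expect_identical(lapply(cv$folds, `[[`, "scores"),
                   lapply(cv2$folds, `[[`, "scores"))
  # summary equals recomputation from stored fold results
  expect_equal(cv$summary$mean[cv$summary$metric == "auc"],
               mean(vapply(cv$folds, `[[`, 0, "auc")))
  # mean ROC is monotone and, for a perfect classifier, saturated at TPR 1
  expect_identical(cv$mean_roc$tpr[101], 1)
  expect_true(all(diff(cv$mean_roc$tpr) >= 0))
  expect_identical(cv$mean_roc$tpr[1], 1)  # all positives above all negatives
})

test_that("Friedman test matches the hand-computed rank statistic", {
  # fixed 5 folds x 4 feature sets with distinct values
  mm <- matrix(c(0.91, 0.88, 0.93, 0.85,
                 0.87, 0.90, 0.95, 0.83,
                 0.92, 0.89, 0.94, 0.86,
                 0.88, 0.91, 0.96, 0.84,
                 0.90, 0.87, 0.97, 0.82), 5, 4, byrow = TRUE)
  res <- friedman_compare(mm)
  # no ties: chi^2 = 12/(nk(k+1)) * sum Rj^2 - 3n(k+1)
  R <- colSums(apply(mm, 1, rank) |> t())
  chi_hand <- 12 / (5 * 4 * 5) * sum(R^2) - 3 * 5 * 5
  expect_equal(res$chisq, chi_hand, tolerance = 1e-8)
  expect_equal(res$p, stats::pchisq(chi_hand, 3, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_identical(res$df, 3L)
  # degenerate: identical columns
  same <- matrix(0.9, 5, 4)
  expect_identical(friedman_compare(same), list(chisq = 0, df = 3L, p = 1))
})

test_that("Friedman p-value falls as one feature set dominates more strongly", {
  set.seed(5)
  ps <- vapply(c(0, 0.15, 0.6), function(shift) {
    mean(replicate(40, {
      mm <- matrix(rnorm(5 * 4, sd = 0.05), 5, 4)
      mm[, 3] <- mm[, 3] + shift
      friedman_compare(mm)$p
    }))
  }, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("exact Wilcoxon matches the reference implementation on tie-free data", {
  set.seed(10)
  mm <- matrix(runif(20, 0.7, 1.0), 5, 4)  # continuous: no tied differences
  p <- wilcoxon_pairwise(mm)
  expect_identical(dim(p), c(4L, 4L))
  expect_identical(diag(p), rep(1, 4) |> stats::setNames(colnames(p)))
  expect_identical(p, t(p))
  for (i in 1:3) for (j in (i + 1):4) {
    ref <- stats::wilcox.test(mm[, i], mm[, j], paired = TRUE,
                              exact = TRUE)$p.value
    expect_equal(p[i, j], ref, tolerance = 1e-8)
  }
  # identical columns give p = 1
  mm2 <- cbind(mm[, 1], mm[, 1], mm[, 2])
  expect_identical(unname(wilcoxon_pairwise(mm2)[1, 2]), 1)
  # fully tied |differences| (where the reference abandons exactness): the
  # enumerated two-sided tail over the 2^5 sign assignments is exhaustive
  tied <- cbind(rep(0, 5), c(-.03, .03, -.03, .03, -.03))
  expect_identical(unname(wilcoxon_pairwise(tied)[1, 2]), 1)
})

test_that("feature-set comparison assembles matrices and test results", {
  tensor <- separable_tensor(n_per_class = 6)
  rep <- compare_feature_sets(tensor, function(fs) tsf_pipeline(n_trees = 5),
                              feature_sets = list(FS3 = feature_set("FS3"),
                                                  FS4 = feature_set("FS4")),
                              folds = 3, seed = 6)
  expect_named(rep$metrics, c("accuracy", "f1", "auc"))
  expect_identical(dim(rep$metrics$auc), c(3L, 2L))
  expect_true(all(vapply(rep$friedman, function(fr) fr$p, 0) >= 0))
  expect_true(all(rep$wilcoxon$auc >= 0 & rep$wilcoxon$auc <= 1))
})
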