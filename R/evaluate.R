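# Cross-validated evaluation: accuracy / F1 / AUC, row-normalized confusion
# matrices, vertically averaged ROC curves, and the nonparametric
# feature-set comparison (Friedman + pairwise exact Wilcoxon signed-rank).

#' Row-normalized confusion matrix
#'
#' Scales each row of a 2 x 2 count matrix (rows = truth, order control then
#' cancer; columns = prediction) by the number of true samples in that class.
#' The diagonal is then (specificity, sensitivity).
#'
#' @param counts 2 x 2 numeric matrix of counts.
#' @return 2 x 2 matrix of rates; a row with no true samples becomes `NA`
#'   with attribute `undefined_rows`.
#' @export
confusion_normalized <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(2L, 2L)),
            all(counts >= 0))
  rs <- rowSums(counts)
  out <- counts / rs
  if (any(rs == 0)) {
    out[rs == 0, ] <- NA_real_
    attr(out, "undefined_rows") <- which(rs == 0)
  }
  dimnames(out) <- list(truth = c("control", "cancer"),
                        predicted = c("control", "cancer"))
  out
}

confusion_counts <- function(truth, predicted) {
  lv <- c("control", "cancer")
  table(factor(as.character(truth), lv), factor(as.character(predicted), lv))
}

# tie-averaged rank (Mann-Whitney) AUC; positive class = cancer
rank_auc <- function(truth, scores) {
  pos <- truth == "cancer"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics
#'
#' Accuracy, F1 for the cancer (positive) class, and AUC computed by the
#' tie-averaged rank formula (equivalent to the trapezoidal ROC area and to
#' the Mann-Whitney pair probability).
#'
#' @param truth true labels (`control`/`cancer`).
#' @param predicted predicted labels.
#' @param scores numeric cancer scores (higher = more cancer-like).
#' @return Named list: `accuracy`, `f1`, `auc` (`auc` is `NA` when the truth
#'   contains a single class), `confusion` (2 x 2 counts).
#' @export
classification_metrics <- function(truth, predicted, scores) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(scores))
  cm <- confusion_counts(truth, predicted)
  acc <- sum(diag(cm)) / sum(cm)
  tp <- cm["cancer", "cancer"]; fp <- cm["control", "cancer"]
  fn <- cm["cancer", "control"]
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = acc, f1 = f1, auc = rank_auc(truth, scores),
       confusion = unclass(cm))
}

#' Stratified cross-validation folds
#'
#' @param labels factor of class labels.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return List of integer index vectors (the held-out sets), each containing
#'   both classes.
#' @export
stratified_folds <- function(labels, folds = 5, seed = 1L) {
  labels <- factor(labels)
  if (min(table(labels)) < folds)
    stop("too few subjects in a class to build ", folds,
         " stratified folds", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  assign_fold <- integer(length(labels))
  for (lv in levels(labels)) {
    pool <- sample(which(labels == lv))
    assign_fold[pool] <- rep_len(seq_len(folds), length(pool))
  }
  lapply(seq_len(folds), function(f) which(assign_fold == f))
}

# per-fold ROC (step interpolation) evaluated on a common FPR grid
roc_on_grid <- function(truth, scores, grid) {
  pos <- truth == "cancer"
  th <- sort(unique(scores), decreasing = TRUE)
  fpr <- c(0, vapply(th, function(s) mean(scores[!pos] >= s), 0), 1)
  tpr <- c(0, vapply(th, function(s) mean(scores[pos] >= s), 0), 1)
  vapply(grid, function(g) max(tpr[fpr <= g]), 0)
}

#' Stratified k-fold cross-validation of a classification pipeline
#'
#' Splits subjects into stratified folds, runs the pipeline's fold-local
#' `fit` (which owns any standardization/augmentation) on each training
#' partition, and evaluates on the held-out fold. Per-fold seeds are derived
#' from `seed`.
#'
#' @param tensor a `cohort_tensor`.
#' @param pipeline a `ts_pipeline` (see [tsf_pipeline()], [lstm_pipeline()]).
#' @param folds number of folds.
#' @param seed integer seed (fold assignment and per-fold fits).
#' @param fpr_grid FPR grid for the vertically averaged ROC.
#' @return List of class `cv_result`: `folds` (per-fold metrics, scores,
#'   truth, confusion), `summary` (mean/sd of each metric), `mean_roc`
#'   (`data.frame` with `fpr`, mean `tpr`), `mean_confusion` (fold-averaged
#'   normalized confusion matrix).
#' @export
cross_validate <- function(tensor, pipeline, folds = 5, seed = 1L,
                           fpr_grid = seq(0, 1, length.out = 101)) {
  stopifnot(inherits(tensor, "cohort_tensor"), inherits(pipeline, "ts_pipeline"))
  fold_idx <- stratified_folds(tensor$labels, folds, seed)
  fold_res <- vector("list", folds)
  roc_mat <- matrix(NA_real_, folds, length(fpr_grid))
  conf_acc <- matrix(0, 2L, 2L)
  for (f in seq_len(folds)) {
    test_idx <- fold_idx[[f]]
    train <- tensor_subset(tensor, setdiff(seq_along(tensor$labels), test_idx))
    test <- tensor_subset(tensor, test_idx)
    fitted <- pipeline$fit(train, seed = seed + f)
    pred <- pipeline$predict(fitted, test)
    met <- classification_metrics(test$labels, pred$label, pred$score)
    fold_res[[f]] <- list(fold = f, accuracy = met$accuracy, f1 = met$f1,
                          auc = met$auc, confusion = met$confusion,
                          scores = pred$score,
                          truth = as.character(test$labels),
                          subjects = test$subjects)
    roc_mat[f, ] <- roc_on_grid(as.character(test$labels), pred$score,
                                fpr_grid)
    conf_acc <- conf_acc + confusion_normalized(met$confusion)
  }
  metrics <- c("accuracy", "f1", "auc")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m)
      mean(vapply(fold_res, `[[`, 0, m), na.rm = TRUE), 0),
    sd = vapply(metrics, function(m)
      stats::sd(vapply(fold_res, `[[`, 0, m)), 0),
    row.names = NULL)
  structure(list(folds = fold_res, summary = summ,
                 mean_roc = data.frame(fpr = fpr_grid,
                                       tpr = colMeans(roc_mat)),
                 mean_confusion = conf_acc / folds,
                 pipeline = pipeline$name, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s):\n", length(x$folds),
              x$pipeline %||% "pipeline"))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' Friedman test across feature sets
#'
#' Rank-based Friedman test (tie-corrected, chi-squared approximation with
#' `ncol - 1` degrees of freedom) on a folds x feature-sets metric matrix.
#' An all-identical matrix degenerates to `chisq = 0`, `p = 1`.
#'
#' @param metric_matrix numeric matrix, rows = folds (blocks), columns =
#'   feature sets (treatments).
#' @return List: `chisq`, `df`, `p`.
#' @export
friedman_compare <- function(metric_matrix) {
  stopifnot(is.matrix(metric_matrix), nrow(metric_matrix) >= 2,
            ncol(metric_matrix) >= 2)
  if (all(apply(metric_matrix, 1L, function(r) max(r) - min(r) == 0))) {
    return(list(chisq = 0, df = ncol(metric_matrix) - 1L, p = 1))
  }
  ft <- stats::friedman.test(metric_matrix)
  chisq <- unname(ft$statistic)
  if (!is.finite(chisq)) # complete ties in every block
    return(list(chisq = 0, df = ncol(metric_matrix) - 1L, p = 1))
  list(chisq = chisq, df = as.integer(ft$parameter), p = ft$p.value)
}

# exact two-sided signed-rank p by enumeration of all 2^m sign assignments;
# zero differences dropped, ties handled by average ranks
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

#' Pairwise Wilcoxon signed-rank tests across feature sets
#'
#' Exact two-sided signed-rank test (full enumeration of the permutation
#' distribution, valid under ties and zero differences) for every pair of
#' columns of a folds x feature-sets metric matrix. No multiple-testing
#' correction is applied. The diagonal is 1 and the matrix is symmetric.
#'
#' @param metric_matrix numeric matrix, rows = folds, columns = feature sets.
#' @param max_exact largest n for exact enumeration; larger samples fall back
#'   to [stats::wilcox.test()].
#' @return Symmetric matrix of p-values.
#' @export
wilcoxon_pairwise <- function(metric_matrix, max_exact = 12) {
  stopifnot(is.matrix(metric_matrix), nrow(metric_matrix) >= 2,
            ncol(metric_matrix) >= 2)
  k <- ncol(metric_matrix)
  nm <- colnames(metric_matrix) %||% paste0("set", seq_len(k))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- metric_matrix[, i] - metric_matrix[, j]
      pij <- if (all(d == 0)) {
        1
      } else if (length(d) <= max_exact) {
        exact_signed_rank_p(d)
      } else {
        suppressWarnings(stats::wilcox.test(metric_matrix[, i],
                                            metric_matrix[, j],
                                            paired = TRUE)$p.value)
      }
      p[i, j] <- p[j, i] <- min(pij, 1)
    }
  }
  p
}

#' Compare feature sets with one pipeline family
#'
#' Runs [cross_validate()] for each feature set, collects per-fold metrics,
#' and applies the Friedman test and pairwise exact Wilcoxon signed-rank
#' tests per metric.
#'
#' @param tensor a `cohort_tensor` containing all features.
#' @param pipeline_for function(features) returning a `ts_pipeline`.
#' @param feature_sets named list of feature-name vectors
#'   (default FS1..FS4).
#' @param folds,seed see [cross_validate()].
#' @return List of class `comparison_report`: `cv` (per set), `metrics`
#'   (list of folds x sets matrices), `friedman` (per metric), `wilcoxon`
#'   (per metric).
#' @export
compare_feature_sets <- function(tensor, pipeline_for,
                                 feature_sets = list(FS1 = feature_set("FS1"),
                                                     FS2 = feature_set("FS2"),
                                                     FS3 = feature_set("FS3"),
                                                     FS4 = feature_set("FS4")),
                                 folds = 5, seed = 1L) {
  cv <- lapply(feature_sets, function(fs)
    cross_validate(select_features(tensor, fs), pipeline_for(fs),
                   folds = folds, seed = seed))
  metric_mats <- lapply(c(accuracy = "accuracy", f1 = "f1", auc = "auc"),
                        function(m) {
    mat <- vapply(cv, function(r) vapply(r$folds, `[[`, 0, m), numeric(folds))
    rownames(mat) <- paste0("fold", seq_len(folds))
    mat
  })
  structure(list(cv = cv,
                 metrics = metric_mats,
                 friedman = lapply(metric_mats, friedman_compare),
                 wilcoxon = lapply(metric_mats, wilcoxon_pairwise)),
            class = "comparison_report")
}
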