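# Interval-based Time Series Forest for multivariate series.
#
# Each tree draws k random temporal intervals per variable, summarizes every
# interval by (mean, sd, slope), and grows a CART-style tree on the resulting
# 3kV features using entropy information gain. The ensemble predicts by
# majority vote; per-split impurity decreases accumulate into a temporal
# importance curve over (feature, time index).

#' Sample random temporal intervals
#'
#' Draws `k` intervals per variable: the length L is uniform on
#' `[lmin, M]`, then the start uniform on `[1, M - L + 1]` (1-based,
#' inclusive ends).
#'
#' @param M series length.
#' @param V number of variables.
#' @param k intervals per variable; default `round(sqrt(M))`.
#' @param lmin minimum interval length, >= 2.
#' @return `data.frame` with columns `variable`, `interval`, `start`, `end`.
#' @export
sample_intervals <- function(M, V, k = NULL, lmin = 3) {
  if (is.null(k)) k <- max(1L, round(sqrt(M)))
  if (lmin > M) stop("lmin must not exceed the series length M", call. = FALSE)
  if (lmin < 2) stop("lmin must be >= 2", call. = FALSE)
  n <- V * k
  # sample() with a length-1 first argument misbehaves; index into the range
  L <- (lmin:M)[sample.int(M - lmin + 1L, n, replace = TRUE)]
  s <- vapply(L, function(l) sample.int(M - l + 1L, 1L), 0L)
  data.frame(variable = rep(seq_len(V), each = k),
             interval = rep(seq_len(k), V),
             start = as.integer(s), end = as.integer(s + L - 1L))
}

#' Interval summary statistics
#'
#' Mean, standard deviation (n-1 denominator), and least-squares slope of the
#' values on the time index, over the inclusive window `[start, end]`.
#'
#' @param x univariate numeric series.
#' @param start,end 1-based inclusive interval bounds, `start < end`.
#' @return Named numeric `c(mean, sd, slope)`.
#' @export
interval_summary <- function(x, start, end) {
  if (start >= end || start < 1 || end > length(x))
    stop("invalid interval [", start, ", ", end, "]", call. = FALSE)
  w <- x[start:end]
  j <- seq_along(w)
  jc <- j - mean(j)
  c(mean = mean(w), sd = stats::sd(w),
    slope = sum(jc * w) / sum(jc^2))
}

#' Per-tree interval feature vector
#'
#' Concatenates the three summary statistics of every sampled interval in
#' (variable, interval, statistic) order; length is exactly `3 * k * V`.
#'
#' @param xi M x V series matrix for one subject.
#' @param intervals a [sample_intervals()] table.
#' @return Numeric vector of length `3 * nrow(intervals)`.
#' @export
tree_features <- function(xi, intervals) {
  stopifnot(is.matrix(xi))
  out <- numeric(3L * nrow(intervals))
  for (r in seq_len(nrow(intervals))) {
    out[3L * (r - 1L) + 1:3] <- interval_summary(
      xi[, intervals$variable[r]], intervals$start[r], intervals$end[r])
  }
  names(out) <- paste0("v", rep(intervals$variable, each = 3L),
                       ".i", rep(intervals$interval, each = 3L),
                       ".", rep(c("mean", "sd", "slope"), nrow(intervals)))
  out
}

# Vectorized interval features for all subjects: N x 3kV matrix.
interval_feature_matrix <- function(values, intervals) {
  N <- dim(values)[1]
  Fm <- matrix(NA_real_, N, 3L * nrow(intervals))
  for (r in seq_len(nrow(intervals))) {
    sub <- values[, intervals$start[r]:intervals$end[r], intervals$variable[r],
                  drop = FALSE]
    dim(sub) <- dim(sub)[1:2]
    L <- ncol(sub)
    mu <- rowMeans(sub)
    sdv <- sqrt(pmax(rowSums(sub^2) - L * mu^2, 0) / (L - 1))
    jc <- seq_len(L) - (L + 1) / 2
    slope <- as.vector(sub %*% jc) / sum(jc^2)
    Fm[, 3L * (r - 1L) + 1:3] <- cbind(mu, sdv, slope)
  }
  Fm
}

entropy <- function(n1, n) {
  p <- n1 / n
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
  h
}

# Best threshold split of one feature column by entropy information gain.
# Returns c(gain, threshold, margin) or NULL if the column is constant.
best_split_column <- function(xcol, y01) {
  n <- length(xcol)
  ord <- order(xcol)
  xs <- xcol[ord]; ys <- y01[ord]
  valid <- which(xs[-n] < xs[-1])
  if (length(valid) == 0L) return(NULL)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  nL <- valid
  n1L <- cum1[valid]
  gain <- entropy(tot1, n) -
    (nL / n) * entropy(n1L, nL) -
    ((n - nL) / n) * entropy(tot1 - n1L, n - nL)
  best <- which(gain >= max(gain) - 1e-12)
  # among equal-gain cuts prefer the widest margin, then the lowest threshold
  gap <- xs[valid + 1L] - xs[valid]
  best <- best[order(-gap[best], xs[valid[best]])][1L]
  i <- valid[best]
  c(gain = gain[best], threshold = (xs[i] + xs[i + 1L]) / 2,
    margin = gap[best] / 2)
}

grow_tree <- function(Fm, y01, max_depth = Inf, depth = 0L,
                      margin_tie_break = FALSE) {
  n <- length(y01)
  n1 <- sum(y01)
  if (n1 == 0L || n1 == n || depth >= max_depth) {
    return(list(leaf = TRUE, prob = n1 / n, n = n))
  }
  cand <- vector("list", ncol(Fm))
  for (j in seq_len(ncol(Fm))) cand[[j]] <- best_split_column(Fm[, j], y01)
  gains <- vapply(cand, function(cc) if (is.null(cc)) -Inf else cc[["gain"]],
                  0)
  if (!any(is.finite(gains)) || max(gains) <= 1e-12) {
    return(list(leaf = TRUE, prob = n1 / n, n = n))
  }
  near <- which(gains >= max(gains) - 1e-12)
  j <- if (margin_tie_break && length(near) > 1L) {
    margins <- vapply(near, function(jj) cand[[jj]][["margin"]], 0)
    near[which.max(margins)]
  } else near[1L]
  th <- cand[[j]][["threshold"]]
  left <- Fm[, j] <= th
  list(leaf = FALSE, feature = j, threshold = th,
       gain = cand[[j]][["gain"]], n = n,
       left = grow_tree(Fm[left, , drop = FALSE], y01[left], max_depth,
                        depth + 1L, margin_tie_break),
       right = grow_tree(Fm[!left, , drop = FALSE], y01[!left], max_depth,
                         depth + 1L, margin_tie_break))
}

predict_tree <- function(node, frow) {
  while (!node$leaf) {
    node <- if (frow[node$feature] <= node$threshold) node$left else node$right
  }
  node$prob
}

#' Fit a Time Series Forest
#'
#' @param tensor a `cohort_tensor` (see [assemble_tensor()]).
#' @param n_trees ensemble size.
#' @param k intervals per variable; default `round(sqrt(M))`.
#' @param lmin minimum interval length.
#' @param max_depth maximum tree depth (default unbounded: trees grow to
#'   purity).
#' @param margin_tie_break if `TRUE`, equal-gain features are split on the
#'   widest-margin threshold (secondary comparator to the entropy gain).
#' @param seed integer seed; the fit is deterministic given
#'   (data, config, seed).
#' @return An object of class `tsf` with per-tree intervals and trees.
#' @export
fit_tsf <- function(tensor, n_trees = 100, k = NULL, lmin = 3,
                    max_depth = Inf, margin_tie_break = FALSE, seed = 1L) {
  stopifnot(inherits(tensor, "cohort_tensor"), n_trees >= 1)
  if (nlevels(droplevels(tensor$labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  M <- dim(tensor$values)[2]; V <- dim(tensor$values)[3]
  if (is.null(k)) k <- max(1L, round(sqrt(M)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  y01 <- as.integer(tensor$labels == "cancer")
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    intervals <- sample_intervals(M, V, k, lmin)
    Fm <- interval_feature_matrix(tensor$values, intervals)
    trees[[b]] <- list(intervals = intervals,
                       tree = grow_tree(Fm, y01, max_depth,
                                        margin_tie_break = margin_tie_break))
  }
  structure(list(trees = trees, M = M, V = V, k = k, lmin = lmin,
                 n_trees = n_trees, features = tensor$features, seed = seed),
            class = "tsf")
}

#' @export
print.tsf <- function(x, ...) {
  cat(sprintf("Time Series Forest: %d trees, k = %d intervals/variable, lmin = %d (M = %d, V = %d)\n",
              x$n_trees, x$k, x$lmin, x$M, x$V))
  invisible(x)
}

#' Predict with a Time Series Forest
#'
#' Majority vote over trees; the score is the fraction of trees voting
#' cancer (usable for ROC). A tied vote is labeled control.
#'
#' @param object a fitted [fit_tsf()] forest.
#' @param tensor a `cohort_tensor` with matching M and V.
#' @param ... unused.
#' @return `data.frame` with `subject`, `score`, `label`.
#' @export
predict.tsf <- function(object, tensor, ...) {
  stopifnot(inherits(tensor, "cohort_tensor"))
  if (dim(tensor$values)[2] != object$M || dim(tensor$values)[3] != object$V)
    stop("tensor shape does not match the fitted forest", call. = FALSE)
  N <- dim(tensor$values)[1]
  votes <- matrix(0L, N, object$n_trees)
  for (b in seq_along(object$trees)) {
    tr <- object$trees[[b]]
    Fm <- interval_feature_matrix(tensor$values, tr$intervals)
    for (i in seq_len(N))
      votes[i, b] <- as.integer(predict_tree(tr$tree, Fm[i, ]) > 0.5)
  }
  score <- rowMeans(votes)
  data.frame(subject = tensor$subjects, score = score,
             label = factor(ifelse(score > 0.5, "cancer", "control"),
                            levels = c("control", "cancer")))
}

#' Temporal importance curve of a fitted forest
#'
#' Credits each split's impurity decrease (weighted by the node size) to
#' every time index inside the split feature's interval, for its variable;
#' sums over trees and normalizes the total mass to 1.
#'
#' @param forest a fitted [fit_tsf()] forest.
#' @return A V x M matrix of class `temporal_importance` (rows named by
#'   feature) summing to 1.
#' @export
temporal_importance <- function(forest) {
  stopifnot(inherits(forest, "tsf"))
  imp <- matrix(0, forest$V, forest$M,
                dimnames = list(forest$features, NULL))
  credit <- function(node, intervals) {
    if (node$leaf) return(invisible(NULL))
    r <- ceiling(node$feature / 3L)
    v <- intervals$variable[r]
    idx <- intervals$start[r]:intervals$end[r]
    imp[v, idx] <<- imp[v, idx] + node$gain * node$n
    credit(node$left, intervals)
    credit(node$right, intervals)
  }
  for (tr in forest$trees) credit(tr$tree, tr$intervals)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  structure(imp, class = c("temporal_importance", "matrix"))
}

#' TSF hyperparameter grid search
#'
#' Stratified k-fold cross-validation over all (n_trees, lmin) combinations;
#' the combination with the highest mean accuracy wins, ties going to the
#' smaller ensemble and then the smaller `lmin`.
#'
#' @param tensor a `cohort_tensor`.
#' @param n_trees_grid ensemble sizes to try.
#' @param lmin_grid minimum interval lengths to try.
#' @param folds number of CV folds.
#' @param k intervals per variable (fixed across the grid).
#' @param seed integer seed (folds and forests).
#' @return List: `best` (list with `n_trees`, `lmin`), `table`
#'   (`data.frame` of mean/sd accuracy per combination).
#' @export
tsf_grid_search <- function(tensor, n_trees_grid = c(100, 200, 300),
                            lmin_grid = c(3, 5, 7), folds = 5, k = NULL,
                            seed = 1L) {
  stopifnot(length(n_trees_grid) >= 1, length(lmin_grid) >= 1)
  grid <- expand.grid(n_trees = n_trees_grid, lmin = lmin_grid)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cv <- cross_validate(tensor,
                         tsf_pipeline(n_trees = grid$n_trees[g],
                                      lmin = grid$lmin[g], k = k),
                         folds = folds, seed = seed)
    acc <- vapply(cv$folds, `[[`, 0, "accuracy")
    data.frame(n_trees = grid$n_trees[g], lmin = grid$lmin[g],
               mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc))
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$mean_accuracy, tab$n_trees, tab$lmin)
  list(best = list(n_trees = tab$n_trees[ord[1]], lmin = tab$lmin[ord[1]]),
       table = tab)
}

#' Cross-validation pipeline wrapper for the TSF
#'
#' Packages [fit_tsf()]/[predict.tsf()] for [cross_validate()]. The TSF path
#' uses the raw (unstandardized, unaugmented) tensor.
#'
#' @param n_trees,k,lmin,max_depth,margin_tie_break see [fit_tsf()].
#' @return A `ts_pipeline` list with `fit(train, seed)` and
#'   `predict(model, test)`.
#' @export
tsf_pipeline <- function(n_trees = 100, k = NULL, lmin = 3, max_depth = Inf,
                         margin_tie_break = FALSE) {
  structure(list(
    name = "tsf",
    fit = function(train, seed) {
      fit_tsf(train, n_trees = n_trees, k = k, lmin = lmin,
              max_depth = max_depth, margin_tie_break = margin_tie_break,
              seed = seed)
    },
    predict = function(model, test) predict(model, test)
  ), class = "ts_pipeline")
}
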