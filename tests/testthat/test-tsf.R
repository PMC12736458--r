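# Interval-based Time Series Forest.

test_that("interval sampling respects bounds and the sqrt(M) heuristic", {
  set.seed(1)
  iv <- sample_intervals(M = 20, V = 5)
  expect_identical(nrow(iv), 5L * 4L)  # k = round(sqrt(20)) = 4
  expect_true(all(iv$start >= 1 & iv$end <= 20))
  expect_true(all(iv$end - iv$start + 1 >= 3))
  # forced full-length interval
  iv2 <- sample_intervals(M = 20, V = 1, k = 3, lmin = 20)
  expect_true(all(iv2$start == 1 & iv2$end == 20))
  expect_error(sample_intervals(M = 10, V = 1, lmin = 11), "exceed")
  expect_error(sample_intervals(M = 10, V = 1, lmin = 1), ">= 2")
  set.seed(42); a <- sample_intervals(20, 5)
  set.seed(42); b <- sample_intervals(20, 5)
  expect_identical(a, b)
})

test_that("interval summaries match closed forms on ramps and constants", {
  s <- interval_summary(c(1, 2, 3, 4, 5), 1, 5)
  expect_equal(unname(s), c(3, sqrt(2.5), 1))
  expect_equal(s[["sd"]], 1.5811, tolerance = 1e-4)
  expect_identical(unname(interval_summary(rep(7, 10), 2, 6)), c(7, 0, 0))
  r <- interval_summary(c(5, 4, 3, 2, 1), 1, 5)
  expect_equal(unname(r), c(3, sqrt(2.5), -1))
  expect_error(interval_summary(1:5, 3, 3), "invalid interval")
})

test_that("per-tree feature vectors have length 3kV in (variable, interval, stat) order", {
  set.seed(2)
  xi <- matrix(rnorm(100), 20, 5)
  for (k in c(1, 2, 4)) {
    iv <- sample_intervals(20, 5, k = k)
    expect_length(tree_features(xi, iv), 3L * k * 5L)
  }
  iv <- sample_intervals(20, 1, k = 1)
  expect_length(tree_features(matrix(rnorm(20), 20, 1), iv), 3L)
  # vectorized cohort features agree with the per-subject path
  iv <- sample_intervals(20, 5, k = 2)
  vals <- array(rnorm(3 * 100), c(3, 20, 5))
  Fm <- thermoseries:::interval_feature_matrix(vals, iv)
  expect_identical(dim(Fm), c(3L, 30L))
  for (i in 1:3)
    expect_equal(unname(Fm[i, ]), unname(tree_features(vals[i, , ], iv)),
                 tolerance = 1e-12)
})

# Independent naive tree oracle: exhaustive O(n^2) split enumeration with
# direct entropy counting, recursion to purity.
naive_entropy <- function(y) {
  p <- mean(y)
  if (p == 0 || p == 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}
naive_tree <- function(Fm, y) {
  if (length(unique(y)) == 1L) return(list(leaf = TRUE, prob = y[1]))
  best <- NULL
  for (j in seq_len(ncol(Fm))) {
    xs <- sort(unique(Fm[, j]))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      th <- (xs[i] + xs[i + 1]) / 2
      l <- Fm[, j] <= th
      gain <- naive_entropy(y) - mean(l) * naive_entropy(y[l]) -
        mean(!l) * naive_entropy(y[!l])
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(gain = gain, j = j, th = th)
      }
    }
  }
  if (is.null(best) || best$gain <= 1e-12)
    return(list(leaf = TRUE, prob = mean(y)))
  l <- Fm[, best$j] <= best$th
  list(leaf = FALSE, j = best$j, th = best$th,
       left = naive_tree(Fm[l, , drop = FALSE], y[l]),
       right = naive_tree(Fm[!l, , drop = FALSE], y[!l]))
}
naive_predict <- function(node, x) {
  while (!node$leaf) node <- if (x[node$j] <= node$th) node$left else node$right
  node$prob
}

test_that("tree growth agrees with an exhaustive split-enumeration oracle", {
  # a case whose best split is unique: predictions must coincide everywhere
  Fm <- cbind(c(0, 1, 2, 10, 11, 12), c(5, 1, 8, 3, 9, 2))
  y <- c(0, 0, 0, 1, 1, 1)
  tree <- thermoseries:::grow_tree(Fm, y)
  oracle <- naive_tree(Fm, y)
  expect_false(tree$leaf)
  expect_identical(tree$feature, oracle$j)
  expect_equal(tree$threshold, oracle$th)
  set.seed(3)
  newx <- matrix(rnorm(40), 20, 2) * 6 + 6
  for (i in 1:20)
    expect_identical(thermoseries:::predict_tree(tree, newx[i, ]) > 0.5,
                     naive_predict(oracle, newx[i, ]) > 0.5)
  # random cases: the achieved root information gain equals the exhaustive
  # maximum (tie-breaks between equally good splits may differ)
  for (rep in 1:5) {
    Fm <- matrix(rnorm(6 * 4), 6, 4)
    y <- c(0, 1, rbinom(4, 1, 0.5))
    tree <- thermoseries:::grow_tree(Fm, y)
    oracle <- naive_tree(Fm, y)
    if (!tree$leaf && !oracle$leaf) {
      l <- Fm[, oracle$j] <= oracle$th
      oracle_gain <- naive_entropy(y) - mean(l) * naive_entropy(y[l]) -
        mean(!l) * naive_entropy(y[!l])
      expect_equal(tree$gain, oracle_gain, tolerance = 1e-12)
    } else {
      expect_identical(tree$leaf, oracle$leaf)
    }
    # both grow to purity on the training points
    for (i in seq_along(y))
      expect_identical(thermoseries:::predict_tree(tree, Fm[i, ]), y[i])
  }
})

test_that("forest votes, scores and tie rule behave as documented", {
  tensor <- separable_tensor(n_per_class = 6)
  fit <- fit_tsf(tensor, n_trees = 15, seed = 4)
  pr <- predict(fit, tensor)
  expect_identical(as.character(pr$label), as.character(tensor$labels))
  expect_true(all(pr$score %in% c(0, 1)))  # all trees agree on separable data
  expect_error(predict(fit, select_features(tensor, "FS2")), "shape")
  # single-class fit is rejected
  expect_error(fit_tsf(tensor_subset(tensor, 1:6), n_trees = 3),
               "both classes")
  # deterministic given (data, config, seed)
  fit2 <- fit_tsf(tensor, n_trees = 15, seed = 4)
  expect_identical(predict(fit2, tensor)$score, pr$score)
})

test_that("temporal importance is a normalized map concentrated on informative frames", {
  # classes diverge only in frames 8..14 of variable 1
  set.seed(5)
  n <- 20; M <- 20
  vals <- array(rnorm(n * M * 2, sd = 0.2), c(n, M, 2))
  labels <- rep(c("control", "cancer"), each = 10)
  vals[labels == "cancer", 8:14, 1] <- vals[labels == "cancer", 8:14, 1] + 3
  dimnames(vals) <- list(paste0("s", 1:n), NULL, c("Tmax", "Tmean"))
  tensor <- thermoseries:::new_cohort_tensor(vals, labels, paste0("s", 1:n),
                                             c("Tmax", "Tmean"))
  fit <- fit_tsf(tensor, n_trees = 50, seed = 6)
  imp <- temporal_importance(fit)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_true(all(imp >= 0))
  # mass concentrates on the divergent variable and window
  expect_gt(sum(imp["Tmax", ]), 0.8)
  peak <- which.max(imp["Tmax", ])
  expect_true(peak >= 6 && peak <= 16)
})

test_that("stump forests credit all importance inside their split intervals", {
  tensor <- separable_tensor(n_per_class = 5)
  fit <- fit_tsf(tensor, n_trees = 5, max_depth = 1, seed = 7)
  imp <- temporal_importance(fit)
  used <- matrix(FALSE, dim(tensor$values)[3], dim(tensor$values)[2])
  for (tr in fit$trees) {
    stopifnot(!tr$tree$leaf)
    r <- ceiling(tr$tree$feature / 3)
    used[tr$intervals$variable[r],
         tr$intervals$start[r]:tr$intervals$end[r]] <- TRUE
  }
  expect_equal(sum(imp[used]), 1, tolerance = 1e-12)
})

test_that("grid search evaluates the full grid and applies the tie rule", {
  tensor <- separable_tensor(n_per_class = 6)
  gs <- tsf_grid_search(tensor, n_trees_grid = c(5, 10, 15),
                        lmin_grid = c(3, 5, 7), folds = 3, seed = 8)
  expect_identical(nrow(gs$table), 9L)
  # perfectly separable: every combination ties at accuracy 1, so the
  # smallest ensemble and smallest lmin win
  expect_true(all(gs$table$mean_accuracy == 1))
  expect_identical(gs$best$n_trees, 5)
  expect_identical(gs$best$lmin, 3)
  one <- tsf_grid_search(tensor, n_trees_grid = 7, lmin_grid = 4, folds = 3,
                         seed = 8)
  expect_identical(one$best, list(n_trees = 7, lmin = 4))
})
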