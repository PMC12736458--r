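# Cohort tensor assembly (N subjects x M frames x V features), feature-set
# selection, fold-safe standardization, and training-set augmentation.

TS_FEATURES <- c("Tmax", "Tmean", "sigma", "q", "d")

#' Canonical feature sets
#'
#' The four descriptor combinations evaluated throughout the package:
#' `FS1 = {q, Tmax, Tmean, sigma, d}`, `FS2 = {q, Tmax, Tmean, sigma}`,
#' `FS3 = {q, Tmax, Tmean}`, `FS4 = {q, Tmax, sigma}`.
#'
#' @param name one of `"FS1"`..`"FS4"`.
#' @return Character vector of feature names.
#' @export
feature_set <- function(name) {
  sets <- list(FS1 = c("q", "Tmax", "Tmean", "sigma", "d"),
               FS2 = c("q", "Tmax", "Tmean", "sigma"),
               FS3 = c("q", "Tmax", "Tmean"),
               FS4 = c("q", "Tmax", "sigma"))
  if (!name %in% names(sets))
    stop("unknown feature set '", name, "'", call. = FALSE)
  sets[[name]]
}

#' Assemble the cohort tensor
#'
#' Stacks per-subject descriptor tables into an N x M x V array with labels.
#'
#' @param tables named list of descriptor `data.frame`s (one per subject, as
#'   returned by [sequence_descriptors()]), each with M rows; labels and
#'   subject ids are read from table attributes unless supplied.
#' @param labels optional character/factor vector of class labels
#'   (`"cancer"`/`"control"`), one per subject.
#' @param subjects optional subject ids.
#' @param features feature columns to keep, in order.
#' @return A `cohort_tensor`: list with `values` (N x M x V array), `labels`
#'   (factor with levels control, cancer), `subjects`, `features`.
#' @export
assemble_tensor <- function(tables, labels = NULL, subjects = NULL,
                            features = TS_FEATURES) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(subjects)) {
    subjects <- vapply(seq_along(tables), function(i) {
      s <- attr(tables[[i]], "subject")
      if (is.null(s)) names(tables)[i] %||% paste0("s", i) else s
    }, "")
  }
  if (is.null(labels)) {
    labels <- vapply(tables, function(tb) {
      l <- attr(tb, "label")
      if (is.null(l)) NA_character_ else l
    }, "")
    if (anyNA(labels)) stop("labels missing and not found in table attributes",
                            call. = FALSE)
  }
  m_per <- vapply(tables, nrow, 0L)
  if (length(unique(m_per)) != 1L) {
    bad <- subjects[m_per != stats::median(m_per)]
    stop("ragged input: subjects with deviating frame counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  missing_cols <- Filter(function(tb) !all(features %in% names(tb)), tables)
  if (length(missing_cols) > 0)
    stop("descriptor tables missing feature columns", call. = FALSE)
  M <- m_per[[1]]; N <- length(tables); V <- length(features)
  values <- array(NA_real_, dim = c(N, M, V),
                  dimnames = list(subjects, NULL, features))
  for (i in seq_len(N))
    values[i, , ] <- as.matrix(tables[[i]][, features])
  if (anyNA(values)) stop("NA values in assembled tensor", call. = FALSE)
  new_cohort_tensor(values, labels, subjects, features)
}

new_cohort_tensor <- function(values, labels, subjects, features) {
  structure(list(values = values,
                 labels = factor(as.character(labels),
                                 levels = c("control", "cancer")),
                 subjects = subjects, features = features),
            class = "cohort_tensor")
}

#' @export
print.cohort_tensor <- function(x, ...) {
  cat(sprintf("cohort_tensor: %d subjects x %d frames x %d features (%s); %s\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              paste(x$features, collapse = ", "),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.cohort_tensor <- function(x) dim(x$values)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset a cohort tensor by subject
#' @param tensor a `cohort_tensor`.
#' @param idx subject indices (integer or logical).
#' @return A `cohort_tensor` with the selected subjects.
#' @export
tensor_subset <- function(tensor, idx) {
  stopifnot(inherits(tensor, "cohort_tensor"))
  new_cohort_tensor(tensor$values[idx, , , drop = FALSE],
                    tensor$labels[idx], tensor$subjects[idx], tensor$features)
}

#' Select a feature subset
#'
#' Reduces V to the requested features, in the order listed.
#'
#' @param tensor a `cohort_tensor`.
#' @param features character vector of feature names (e.g. [feature_set()]),
#'   or a set name `"FS1"`..`"FS4"`.
#' @return A `cohort_tensor` with reduced V.
#' @export
select_features <- function(tensor, features) {
  stopifnot(inherits(tensor, "cohort_tensor"))
  if (is.character(features) && length(features) == 1L &&
      grepl("^FS[1-4]$", features))
    features <- feature_set(features)
  if (anyDuplicated(features))
    stop("duplicate feature names in selection", call. = FALSE)
  unknown <- setdiff(features, tensor$features)
  if (length(unknown) > 0)
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  new_cohort_tensor(tensor$values[, , features, drop = FALSE],
                    tensor$labels, tensor$subjects, features)
}

#' Fold-safe feature standardization
#'
#' Per-feature z-scoring with moments computed on the training tensor only
#' (pooled over subjects and frames) and applied unchanged to any held-out
#' tensors, preventing information leakage across CV folds.
#'
#' @param train a `cohort_tensor` used to fit the moments.
#' @param apply_to optional (list of) `cohort_tensor`(s) to transform with
#'   the training moments.
#' @return List: `train` (standardized), `applied` (list of standardized
#'   tensors), `center`, `scale` (named per feature).
#' @export
standardize_tensor <- function(train, apply_to = list()) {
  stopifnot(inherits(train, "cohort_tensor"))
  if (inherits(apply_to, "cohort_tensor")) apply_to <- list(apply_to)
  V <- length(train$features)
  center <- scale <- stats::setNames(numeric(V), train$features)
  for (v in seq_len(V)) {
    x <- train$values[, , v]
    center[v] <- mean(x)
    s <- stats::sd(as.vector(x))
    if (!is.finite(s) || s < 1e-12) {
      warning("feature '", train$features[v],
              "' has (near-)zero variance; scale floored", call. = FALSE)
      s <- 1e-12
    }
    scale[v] <- s
  }
  zscore <- function(tensor) {
    out <- tensor$values
    for (v in seq_len(V)) out[, , v] <- (out[, , v] - center[v]) / scale[v]
    new_cohort_tensor(out, tensor$labels, tensor$subjects, tensor$features)
  }
  list(train = zscore(train), applied = lapply(apply_to, zscore),
       center = center, scale = scale)
}

#' Gaussian-noise augmentation of one sequence
#'
#' Adds i.i.d. zero-mean Gaussian noise (default sd 0.05) independently to
#' each feature value of an M x V sequence matrix.
#'
#' @param x M x V numeric matrix.
#' @param sd noise standard deviation, >= 0.
#' @return Matrix of the same shape.
#' @export
augment_noise <- function(x, sd = 0.05) {
  stopifnot(is.matrix(x), is.numeric(sd), sd >= 0)
  if (sd == 0) return(x)
  x + matrix(stats::rnorm(length(x), sd = sd), nrow(x), ncol(x))
}

#' Temporal-shift augmentation of one sequence
#'
#' Shifts the series forward by `s` frames; the vacated initial frames repeat
#' the earliest available measurement. Length is unchanged.
#'
#' @param x M x V numeric matrix.
#' @param s shift in frames (non-negative integer < M; the standard policy
#'   draws from \{1, 2\}).
#' @return Matrix of the same shape.
#' @export
augment_shift <- function(x, s) {
  stopifnot(is.matrix(x), length(s) == 1L, s == round(s), s >= 0)
  M <- nrow(x)
  if (s >= M) stop("shift s must be smaller than the series length",
                   call. = FALSE)
  if (s == 0) return(x)
  x[pmax(seq_len(M) - s, 1L), , drop = FALSE]
}

#' Expand a training tensor by augmentation
#'
#' Each original sequence contributes itself, one Gaussian-noise copy, and
#' one temporal-shift copy (shift drawn uniformly from \{1, 2\}), tripling
#' the training partition exactly. Labels are copied; augmented subjects get
#' `_noise` / `_shift` id suffixes. Apply to training folds only.
#'
#' @param tensor a `cohort_tensor` (training partition).
#' @param noise_sd Gaussian augmentation sd.
#' @param seed integer seed making the expansion deterministic.
#' @return A `cohort_tensor` with 3x the subjects.
#' @export
expand_training_set <- function(tensor, noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(tensor, "cohort_tensor"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  N <- dim(tensor$values)[1]; M <- dim(tensor$values)[2]
  V <- dim(tensor$values)[3]
  values <- array(NA_real_, dim = c(3L * N, M, V))
  labels <- character(3L * N); subjects <- character(3L * N)
  for (i in seq_len(N)) {
    xi <- tensor$values[i, , , drop = TRUE]
    if (V == 1L) xi <- matrix(xi, M, 1L)
    j <- 3L * (i - 1L)
    values[j + 1L, , ] <- xi
    values[j + 2L, , ] <- augment_noise(xi, sd = noise_sd)
    values[j + 3L, , ] <- augment_shift(xi, s = sample(1:2, 1L))
    labels[j + 1:3] <- as.character(tensor$labels[i])
    subjects[j + 1:3] <- paste0(tensor$subjects[i], c("", "_noise", "_shift"))
  }
  dimnames(values) <- list(subjects, NULL, tensor$features)
  new_cohort_tensor(values, labels, subjects, tensor$features)
}
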