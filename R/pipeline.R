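# End-to-end pipeline: generate (or read) thermogram sequences, extract
# descriptors, assemble the tensor, cross-validate the classifiers, and write
# features, metrics, and a reproducibility manifest.

#' Run the full analysis pipeline
#'
#' Executes generate/read -> descriptor extraction -> tensor assembly ->
#' classifier cross-validation -> metrics, writing `features.csv` (+ JSON
#' sidecar), `metrics.json`, and `manifest.json` to `output_dir`.
#'
#' @param output_dir directory for artifacts (created if needed).
#' @param input_dir directory of thermogram sequences (see [read_cohort()]);
#'   `NULL` (default) generates a synthetic cohort instead.
#' @param phantom a [phantom_config()] used when `input_dir` is `NULL`; its
#'   `seed` is overridden by `seed`.
#' @param features feature set name (`"FS1"`..`"FS4"`) or character vector.
#' @param classifier `"both"`, `"tsf"`, or `"lstm"`.
#' @param folds CV folds.
#' @param seed master seed.
#' @param tsf_args list of arguments for [tsf_pipeline()].
#' @param lstm_cfg an [lstm_config()] for the LSTM path.
#' @param lstm_augment apply the 3x training augmentation in the LSTM path.
#' @param env a [thermal_environment()] for descriptor extraction.
#' @param plots also render the mean normalized confusion matrix (and, for
#'   the TSF, the temporal importance map) as PNG.
#' @return Invisibly, a list with `tensor` and the `cv_result` per
#'   classifier.
#' @export
run_pipeline <- function(output_dir,
                         input_dir = NULL,
                         phantom = phantom_config(),
                         features = "FS1",
                         classifier = c("both", "tsf", "lstm"),
                         folds = 5,
                         seed = 1L,
                         tsf_args = list(),
                         lstm_cfg = lstm_config(),
                         lstm_augment = TRUE,
                         env = thermal_environment(),
                         plots = FALSE) {
  classifier <- match.arg(classifier)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (is.null(input_dir)) {
    phantom$seed <- as.integer(seed)
    generate_cohort(phantom)
  } else {
    read_cohort(input_dir)
  }

  tables <- cohort_descriptors(cohort, env = env)
  tensor <- assemble_tensor(tables)
  write_tensor_csv(tensor, file.path(output_dir, "features.csv"))
  tensor_fs <- select_features(tensor, features)

  results <- list(tensor = tensor_fs)
  metrics_out <- list()
  if (classifier %in% c("both", "tsf")) {
    cv <- cross_validate(tensor_fs, do.call(tsf_pipeline, tsf_args),
                         folds = folds, seed = seed)
    results$tsf <- cv
    metrics_out$tsf <- cv_to_json(cv)
  }
  if (classifier %in% c("both", "lstm")) {
    cv <- cross_validate(tensor_fs,
                         lstm_pipeline(lstm_cfg, augment = lstm_augment),
                         folds = folds, seed = seed)
    results$lstm <- cv
    metrics_out$lstm <- cv_to_json(cv)
  }
  atomic_write(file.path(output_dir, "metrics.json"), function(tmp)
    jsonlite::write_json(metrics_out, tmp, auto_unbox = TRUE, digits = NA))

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, folds = folds, features = features,
    classifier = classifier,
    input = if (is.null(input_dir)) "synthetic" else input_dir,
    phantom = if (is.null(input_dir))
      utils::modifyList(unclass(phantom),
                        list(kinetics = NULL, source = NULL, env = NULL))
      else NULL,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("thermoseries")))
  atomic_write(file.path(output_dir, "manifest.json"), function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA))

  if (plots) render_plots(results, output_dir)
  invisible(results)
}

cv_to_json <- function(cv) {
  list(summary = cv$summary,
       folds = lapply(cv$folds, function(f)
         list(fold = f$fold, accuracy = f$accuracy, f1 = f$f1, auc = f$auc)),
       mean_confusion = cv$mean_confusion)
}

render_plots <- function(results, output_dir) {
  for (nm in intersect(c("tsf", "lstm"), names(results))) {
    path <- file.path(output_dir, paste0("confusion_", nm, ".png"))
    grDevices::png(path, width = 480, height = 480)
    cm <- results[[nm]]$mean_confusion
    graphics::image(1:2, 1:2, t(cm[2:1, ]), col = grDevices::hcl.colors(64),
                    axes = FALSE, xlab = "predicted", ylab = "truth",
                    main = paste("Mean normalized confusion -", toupper(nm)))
    graphics::axis(1, 1:2, colnames(cm)); graphics::axis(2, 1:2, rev(rownames(cm)))
    for (i in 1:2) for (j in 1:2)
      graphics::text(j, 3 - i, sprintf("%.2f", cm[i, j]), cex = 2)
    grDevices::dev.off()
  }
  invisible(NULL)
}
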