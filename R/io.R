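# Readers and writers: plain-text temperature matrices, RoI masks (text grid
# or PNG), per-subject sequence directories with a JSON sidecar, and the
# long-format tensor CSV. All writes are atomic (write temp, then rename).

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("atomic rename to '", path, "' failed", call. = FALSE)
  invisible(path)
}

#' Write a temperature matrix as plain text
#'
#' Whitespace-delimited floats, one frame row per line; full double
#' precision so a write/read round trip is bit-identical.
#'
#' @param frame numeric matrix (deg C).
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_temperature_matrix <- function(frame, path) {
  stopifnot(is.matrix(frame))
  atomic_write(path, function(tmp) {
    lines <- apply(unclass(frame), 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
    writeLines(lines, tmp)
  })
}

#' Read a plain-text temperature matrix
#'
#' @param path whitespace-delimited numeric grid file.
#' @param pitch optional pixel pitch (m/pixel) attached as an attribute.
#' @return Temperature matrix of class `thermal_frame`.
#' @export
read_temperature_matrix <- function(path, pitch = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty temperature matrix: ", path,
                                call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop("non-numeric token in ", path, " at line ", i, call. = FALSE)
    vals
  })
  w <- lengths(rows)
  if (length(unique(w)) != 1L)
    stop("ragged temperature matrix in ", path, ": line ",
         which(w != w[1])[1], " has ", w[which(w != w[1])[1]],
         " values, expected ", w[1], call. = FALSE)
  m <- do.call(rbind, rows)
  structure(m, pitch = pitch, class = c("thermal_frame", "matrix"))
}

#' Write a binary RoI mask
#'
#' @param mask logical matrix.
#' @param path output file; a `.png` suffix writes an image, anything else a
#'   0/1 text grid.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    atomic_write(path, function(tmp) png::writePNG(mask * 1, tmp))
  } else {
    atomic_write(path, function(tmp)
      writeLines(apply(mask * 1L, 1L, paste, collapse = " "), tmp))
  }
}

#' Read a binary RoI mask
#'
#' Accepts a PNG image (any nonzero pixel is inside the RoI; multi-channel
#' images use the first channel) or a 0/1 whitespace-delimited text grid.
#'
#' @param path mask file.
#' @param dim expected `c(rows, cols)`, checked when supplied.
#' @return Logical matrix.
#' @export
read_mask <- function(path, dim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(base::dim(img)) == 3L) img <- img[, , 1L]
    m <- img > 0
  } else {
    m <- unclass(read_temperature_matrix(path)) != 0
  }
  if (!is.null(dim) && !all(base::dim(m) == dim))
    stop("mask shape ", paste(base::dim(m), collapse = "x"),
         " does not match frames ", paste(dim, collapse = "x"),
         call. = FALSE)
  m
}

#' Write a thermogram sequence to a directory
#'
#' Layout: `frame_01.txt ... frame_MM.txt` (plain-text temperature matrices),
#' `mask.png`, and `meta.json` (subject, label, times, pitch, seed).
#'
#' @param sequence a `thermogram_sequence`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sequence <- function(sequence, dir) {
  stopifnot(inherits(sequence, "thermogram_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sequence$frames))
    write_temperature_matrix(sequence$frames[[i]],
                             file.path(dir, sprintf("frame_%02d.txt", i)))
  write_mask(sequence$mask, file.path(dir, "mask.png"))
  meta <- list(subject = sequence$subject, label = sequence$label,
               times = sequence$times, pitch = sequence$pitch,
               seed = sequence$seed)
  atomic_write(file.path(dir, "meta.json"), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA))
  invisible(dir)
}

#' Read a thermogram sequence from a directory
#'
#' @param dir directory produced by [write_sequence()] (or following the same
#'   layout).
#' @return A `thermogram_sequence`.
#' @export
read_sequence <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json in ", dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  meta$times <- as.numeric(meta$times)
  meta$pitch <- as.numeric(meta$pitch)
  frame_files <- sort(list.files(dir, pattern = "^frame_\\d+\\.txt$",
                                 full.names = TRUE))
  if (length(frame_files) == 0L) stop("no frames in ", dir, call. = FALSE)
  frames <- lapply(frame_files, read_temperature_matrix, pitch = meta$pitch)
  mask_path <- if (file.exists(file.path(dir, "mask.png")))
    file.path(dir, "mask.png") else file.path(dir, "mask.txt")
  if (!file.exists(mask_path)) stop("missing mask file: ", mask_path,
                                    call. = FALSE)
  mask <- read_mask(mask_path, dim = dim(frames[[1]]))
  structure(list(frames = frames, times = meta$times, mask = mask,
                 label = meta$label, subject = meta$subject,
                 pitch = meta$pitch, seed = meta$seed),
            class = "thermogram_sequence")
}

#' Write / read a whole cohort
#'
#' One subdirectory per subject, named by subject id.
#'
#' @param cohort a `thermogram_cohort`.
#' @param dir cohort directory.
#' @return `write_cohort`: the directory, invisibly. `read_cohort`: a
#'   `thermogram_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "thermogram_cohort"))
  for (s in cohort) write_sequence(s, file.path(dir, s$subject))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  if (length(subs) == 0L) stop("no subject directories in ", dir,
                               call. = FALSE)
  seqs <- lapply(subs, read_sequence)
  names(seqs) <- vapply(seqs, `[[`, "", "subject")
  structure(seqs, class = "thermogram_cohort")
}

#' Persist a cohort tensor as long-format CSV
#'
#' Columns: `subject`, `frame`, `feature`, `value`, `label`; a JSON sidecar
#' (`<path>.json`) records the feature order and dimensions for an exact
#' round trip.
#'
#' @param tensor a `cohort_tensor`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_tensor_csv <- function(tensor, path) {
  stopifnot(inherits(tensor, "cohort_tensor"))
  d <- dim(tensor$values)
  df <- data.frame(
    subject = rep(tensor$subjects, times = d[2] * d[3]),
    frame = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    feature = rep(tensor$features, each = d[1] * d[2]),
    value = as.vector(tensor$values),
    label = rep(as.character(tensor$labels), times = d[2] * d[3]))
  atomic_write(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE))
  atomic_write(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(list(subjects = tensor$subjects,
                              features = tensor$features,
                              n_frames = d[2]),
                         tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Read a cohort tensor from long-format CSV
#'
#' @param path CSV written by [write_tensor_csv()].
#' @return A `cohort_tensor`.
#' @export
read_tensor_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  N <- length(meta$subjects); M <- meta$n_frames
  V <- length(meta$features)
  values <- array(NA_real_, c(N, M, V),
                  dimnames = list(meta$subjects, NULL, meta$features))
  si <- match(df$subject, meta$subjects)
  vi <- match(df$feature, meta$features)
  values[cbind(si, df$frame, vi)] <- df$value
  labels <- df$label[match(meta$subjects, df$subject)]
  if (anyNA(values)) stop("incomplete tensor CSV: ", path, call. = FALSE)
  new_cohort_tensor(values, labels, meta$subjects, meta$features)
}
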