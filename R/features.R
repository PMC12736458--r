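# Per-frame physiological descriptors via hotspot localization, radial
# profiling around the hottest pixel, and the closed-form inversion of the
# point-source surface temperature law (depth d, intensity q, radius R).

degenerate_error <- function(msg) {
  structure(class = c("thermoseries_degenerate", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Construct a radial profile directly
#'
#' For analytically known profiles (e.g. the continuous point-source law
#' evaluated at the fixed radial distance) the inversion can be applied
#' without any pixel sampling.
#'
#' @param Tmax temperature at the hotspot (deg C).
#' @param Ta temperature at radial distance `a` (deg C).
#' @param Te surround temperature (deg C).
#' @param a radial distance (m), > 0.
#' @param center optional hotspot pixel coordinates.
#' @return A `radial_profile`.
#' @export
radial_profile <- function(Tmax, Ta, Te, a = 0.0168, center = c(NA, NA)) {
  stopifnot(is.numeric(Tmax), is.numeric(Ta), is.numeric(Te), a > 0)
  structure(list(center = center, Tmax = Tmax, Ta = Ta, Te = Te, a = a),
            class = "radial_profile")
}

#' Locate the hotspot of a frame
#'
#' Returns the maximum-temperature pixel within the RoI. Ties are broken
#' deterministically by the smallest row-major index
#' (`(row - 1) * ncol + col`).
#'
#' @param frame temperature matrix (deg C).
#' @param mask logical matrix of the same shape, `TRUE` inside the RoI.
#' @return List with `center` (`c(row, col)`) and `Tmax`.
#' @export
locate_hotspot <- function(frame, mask) {
  stopifnot(is.matrix(frame), is.matrix(mask), all(dim(frame) == dim(mask)))
  mask <- mask & is.finite(frame)
  if (!any(mask)) stop("empty RoI mask", call. = FALSE)
  vals <- ifelse(mask, frame, -Inf)
  tmax <- max(vals)
  cand <- which(vals == tmax, arr.ind = TRUE)
  rm_idx <- (cand[, 1] - 1) * ncol(frame) + cand[, 2]
  win <- cand[which.min(rm_idx), , drop = TRUE]
  list(center = as.integer(win), Tmax = tmax)
}

#' Sample the radial temperature profile around a hotspot
#'
#' Estimates `T(a)`, the temperature at metric radial distance `a` from the
#' hotspot, either as the mean over the masked annulus
#' `|dist - a| <= pitch/2` (default, consistent with the radially symmetric
#' source model) or as the mean of the two horizontal samples at column
#' offsets of `+/- a` ("line" mode). The surround temperature `Te` is
#' estimated from the frame (default: 10th percentile of masked
#' temperatures) or fixed by `Te`.
#'
#' @param frame temperature matrix (deg C).
#' @param mask logical RoI mask.
#' @param center hotspot pixel `c(row, col)`.
#' @param a radial distance (m), > 0.
#' @param pitch pixel pitch (m/pixel).
#' @param mode `"annulus"` or `"line"`.
#' @param Te optional fixed surround temperature; `NULL` to estimate.
#' @param te_quantile quantile of masked temperatures used as the `Te`
#'   estimate.
#' @return A `radial_profile`: list with `center`, `Tmax`, `Ta`, `Te`, `a`.
#' @export
sample_profile <- function(frame, mask, center, a = 0.0168, pitch,
                           mode = c("annulus", "line"), Te = NULL,
                           te_quantile = 0.1) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(frame), all(dim(frame) == dim(mask)),
            length(center) == 2L, a > 0, pitch > 0)
  h <- nrow(frame); w <- ncol(frame)
  Tmax <- frame[center[1], center[2]]

  if (mode == "annulus") {
    rr <- (matrix(seq_len(h), h, w) - center[1]) * pitch
    cc <- (matrix(seq_len(w), h, w, byrow = TRUE) - center[2]) * pitch
    dist <- sqrt(rr^2 + cc^2)
    sel <- mask & abs(dist - a) <= pitch / 2
    if (!any(sel)) {
      dmax <- max(dist[mask])
      stop(sprintf(
        "annulus at a = %g m does not intersect the mask (max achievable radius %g m)",
        a, dmax), call. = FALSE)
    }
    Ta <- mean(frame[sel])
  } else {
    off <- round(a / pitch)
    cols <- center[2] + c(-off, off)
    ok <- cols >= 1 & cols <= w
    ok[ok] <- mask[center[1], cols[ok]]
    if (!any(ok))
      stop(sprintf("line samples at +/- %g m fall outside the mask", a),
           call. = FALSE)
    Ta <- mean(frame[center[1], cols[ok]])
  }
  if (is.null(Te))
    Te <- unname(stats::quantile(frame[mask], te_quantile, names = FALSE))
  structure(list(center = center, Tmax = Tmax, Ta = Ta, Te = Te, a = a),
            class = "radial_profile")
}

#' Estimate source depth from a radial profile
#'
#' Inverts the point-source surface law:
#' `d = a * sqrt((T(a) - Te) / (Tmax - T(a)))`. When the profile was produced
#' by a finite-radius spherical source, the estimate equals `d + R`.
#'
#' @param profile a [sample_profile()] result.
#' @return Depth in m.
#' @export
estimate_depth <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  with(profile, {
    if (!(Tmax > Ta) || !(Ta > Te))
      stop(degenerate_error(sprintf(
        "degenerate profile: need Tmax (%.4g) > T(a) (%.4g) > Te (%.4g)",
        Tmax, Ta, Te)))
    a * sqrt((Ta - Te) / (Tmax - Ta))
  })
}

#' Estimate source intensity from a radial profile
#'
#' Inverts the point-source surface law:
#' `q = 4 pi h0 (T(a) - Te) (Tmax - Te) a^2 / (Tmax - T(a))`.
#'
#' @param profile a [sample_profile()] result.
#' @param env a [thermal_environment()] supplying `h0`.
#' @return Intensity in W.
#' @export
estimate_intensity <- function(profile, env = thermal_environment()) {
  stopifnot(inherits(profile, "radial_profile"),
            inherits(env, "thermal_environment"))
  with(profile, {
    if (!(Tmax > Ta) || !(Ta > Te))
      stop(degenerate_error(sprintf(
        "degenerate profile: need Tmax (%.4g) > T(a) (%.4g) > Te (%.4g)",
        Tmax, Ta, Te)))
    4 * pi * env$h0 * (Ta - Te) * (Tmax - Te) * a^2 / (Tmax - Ta)
  })
}

#' Equivalent source radius from intensity
#'
#' `R = (q / (Qm * At))^(1/3)`, the radius of a sphere whose metabolic heat
#' production at rate `Qm` matches the estimated intensity.
#'
#' @param q source intensity (W), >= 0.
#' @param env a [thermal_environment()] supplying `Qm` and `At`.
#' @return Radius in m.
#' @export
estimate_radius <- function(q, env = thermal_environment()) {
  stopifnot(inherits(env, "thermal_environment"))
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0))
    stop("q must be finite and non-negative", call. = FALSE)
  (q / (env$Qm * env$At))^(1 / 3)
}

#' Per-frame physiological descriptors
#'
#' Computes the five-element feature vector of one frame: `Tmax`, `Tmean`
#' (mask mean), `sigma` (mask sd, n-1 denominator), and the D-I-R estimates
#' `q` and `d`; the equivalent radius `R` is returned as an auxiliary value.
#' A degenerate radial profile (no thermal contrast) yields `NA` for `q`,
#' `d`, `R` and `degenerate = TRUE`.
#'
#' @param frame temperature matrix (deg C).
#' @param mask logical RoI mask.
#' @param env a [thermal_environment()].
#' @param a radial profile distance (m).
#' @param pitch pixel pitch (m/pixel); taken from the frame's `pitch`
#'   attribute when `NULL`.
#' @param mode radial sampling mode, see [sample_profile()].
#' @param Te optional fixed surround temperature.
#' @param te_quantile see [sample_profile()].
#' @return Named list: `Tmax`, `Tmean`, `sigma`, `q`, `d`, `R`, `degenerate`.
#' @export
frame_descriptors <- function(frame, mask, env = thermal_environment(),
                              a = 0.0168, pitch = NULL,
                              mode = "annulus", Te = NULL, te_quantile = 0.1) {
  if (is.null(pitch)) pitch <- attr(frame, "pitch")
  if (is.null(pitch)) stop("pixel pitch not supplied", call. = FALSE)
  frame <- unclass(frame)
  hs <- locate_hotspot(frame, mask)
  vals <- frame[mask]
  out <- list(Tmax = hs$Tmax, Tmean = mean(vals), sigma = stats::sd(vals),
              q = NA_real_, d = NA_real_, R = NA_real_, degenerate = FALSE)
  prof <- tryCatch(
    sample_profile(frame, mask, hs$center, a = a, pitch = pitch, mode = mode,
                   Te = Te, te_quantile = te_quantile),
    error = function(e) e)
  if (inherits(prof, "error")) {
    out$degenerate <- TRUE
    return(out)
  }
  qd <- tryCatch(list(q = estimate_intensity(prof, env),
                      d = estimate_depth(prof)),
                 thermoseries_degenerate = function(e) NULL)
  if (is.null(qd)) {
    out$degenerate <- TRUE
  } else {
    out$q <- qd$q
    out$d <- qd$d
    out$R <- estimate_radius(qd$q, env)
  }
  out
}

#' Descriptor time series of a thermogram sequence
#'
#' Applies [frame_descriptors()] to every frame. Frames with a degenerate
#' profile keep their temperature statistics but have `q`, `d`, `R` carried
#' forward from the most recent non-degenerate frame (leading gaps are filled
#' backward from the first valid frame), so every series has length M; the
#' `degenerate` column flags affected frames.
#'
#' @param sequence a `thermogram_sequence` (see [generate_sequence()] /
#'   [read_sequence()]).
#' @param env a [thermal_environment()].
#' @param ... passed to [frame_descriptors()].
#' @return `data.frame` with columns `frame`, `time`, `Tmax`, `Tmean`,
#'   `sigma`, `q`, `d`, `R`, `degenerate`.
#' @export
sequence_descriptors <- function(sequence, env = thermal_environment(), ...) {
  stopifnot(inherits(sequence, "thermogram_sequence"))
  rows <- lapply(seq_along(sequence$frames), function(i) {
    fd <- frame_descriptors(sequence$frames[[i]], sequence$mask, env,
                            pitch = sequence$pitch, ...)
    data.frame(frame = i, time = sequence$times[i], Tmax = fd$Tmax,
               Tmean = fd$Tmean, sigma = fd$sigma, q = fd$q, d = fd$d,
               R = fd$R, degenerate = fd$degenerate)
  })
  df <- do.call(rbind, rows)
  for (col in c("q", "d", "R")) df[[col]] <- fill_gaps(df[[col]])
  if (anyNA(df[c("q", "d", "R")]))
    stop("all frames of subject '", sequence$subject,
         "' have degenerate profiles", call. = FALSE)
  attr(df, "subject") <- sequence$subject
  attr(df, "label") <- sequence$label
  df
}

# last-observation-carried-forward, then backward fill for leading NAs
fill_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) return(x)
  idx <- findInterval(seq_along(x), ok)
  out <- x[ok[pmax(idx, 1L)]]
  out
}

#' Descriptor tables for a whole cohort
#'
#' @param cohort a `thermogram_cohort` (see [generate_cohort()]).
#' @param env a [thermal_environment()].
#' @param ... passed to [frame_descriptors()].
#' @return Named list of per-subject descriptor `data.frame`s.
#' @export
cohort_descriptors <- function(cohort, env = thermal_environment(), ...) {
  stopifnot(inherits(cohort, "thermogram_cohort"))
  lapply(cohort, sequence_descriptors, env = env, ...)
}
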