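# Synthetic cold-stress thermogram sequences.
#
# Each frame is composed as
#   baseline rewarming (exponential recovery law, class kinetics)
#   + hotspot bump (point-source surface law around a class-dependent center)
#   + smooth spatial heterogeneity field (fixed per sequence)
#   + i.i.d. Gaussian sensor noise (redrawn per frame).
# The hotspot intensity follows the class rewarming factor so that the q(t)
# series carries temporal information: q(t) = q * (floor + (1-floor)(1-e^-t/tau)).

#' Phantom cohort configuration
#'
#' Defines the study conditions emulated by the generator: 20-frame
#' post-cold-stress sequences sampled every 15 s, group recovery kinetics
#' taken from cohort-level exponential fits (control T0 32.14 / Tinf 32.63 /
#' tau 57.76 s; cancer 32.69 / 33.80 / 56.26 s), a localized spherical-source
#' hotspot present in the cancer class and nearly absent in controls, larger
#' spatial heterogeneity and an off-center hotspot (asymmetry) in the cancer
#' class, and additive sensor noise.
#'
#' @param grid frame size in pixels, `c(rows, cols)`.
#' @param pitch pixel pitch (m/pixel).
#' @param n_frames number of frames M per sequence.
#' @param frame_interval sampling interval (s).
#' @param kinetics named list (`control`, `cancer`) of [recovery_kinetics()].
#' @param source named list (`control`, `cancer`) of [heat_source()]; the
#'   control intensity is kept near zero (hotspot "absent").
#' @param hotspot_offset named list of integer `c(row, col)` pixel offsets of
#'   the hotspot from the mask center (class asymmetry).
#' @param heterogeneity_sd named numeric: spatial standard deviation (deg C)
#'   of the smooth per-sequence heterogeneity field.
#' @param heterogeneity_scale Gaussian blur sigma (pixels) of the field.
#' @param noise_sd sensor noise standard deviation (deg C) per pixel/frame.
#' @param q_floor fraction of the source intensity present at t = 0; the rest
#'   follows the class rewarming factor.
#' @param subject_sd per-subject biological variability: `level` (deg C, sd of
#'   a shared offset added to T0 and Tinf), `amplitude` (deg C, sd of an extra
#'   offset on Tinf), `tau_lnsd` (sd of log tau), `q_lnsd` (sd of log source
#'   intensity).
#' @param n_per_class subjects per class.
#' @param env a [thermal_environment()]; its `Te` is unused by the generator
#'   (the instantaneous baseline plays that role) but `h0` shapes the bump.
#' @param seed master seed for cohort generation.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(96, 96),
                           pitch = 0.001,
                           n_frames = 20,
                           frame_interval = 15,
                           kinetics = list(
                             control = recovery_kinetics(32.14, 32.63, 57.76),
                             cancer  = recovery_kinetics(32.69, 33.80, 56.26)
                           ),
                           source = list(
                             control = heat_source(q = 0.01,  d = 0.02),
                             cancer  = heat_source(q = 0.132, d = 0.02)
                           ),
                           hotspot_offset = list(
                             control = c(0L, 0L),
                             cancer  = c(10L, 8L)
                           ),
                           heterogeneity_sd = c(control = 0.90, cancer = 1.00),
                           heterogeneity_scale = 6,
                           noise_sd = 0.05,
                           q_floor = 0.3,
                           subject_sd = c(level = 0.25, amplitude = 0.15,
                                          tau_lnsd = 0.08, q_lnsd = 0.15),
                           n_per_class = 25,
                           env = thermal_environment(),
                           seed = 1L) {
  stopifnot(length(grid) == 2L, all(grid >= 8), pitch > 0, n_frames >= 1,
            frame_interval > 0, n_per_class >= 1,
            all(c("control", "cancer") %in% names(kinetics)),
            all(c("control", "cancer") %in% names(source)),
            noise_sd >= 0, q_floor >= 0, q_floor <= 1)
  cfg <- structure(list(
    grid = as.integer(grid), pitch = pitch, n_frames = as.integer(n_frames),
    frame_interval = frame_interval, kinetics = kinetics, source = source,
    hotspot_offset = hotspot_offset, heterogeneity_sd = heterogeneity_sd,
    heterogeneity_scale = heterogeneity_scale, noise_sd = noise_sd,
    q_floor = q_floor, subject_sd = subject_sd,
    n_per_class = as.integer(n_per_class), env = env,
    seed = as.integer(seed), profile_radius = 0.0168
  ), class = "phantom_config")
  for (cls in c("control", "cancer")) {
    ctr <- phantom_hotspot_center(cfg, cls)
    m <- phantom_mask(cfg)
    if (ctr[1] < 1 || ctr[1] > grid[1] || ctr[2] < 1 || ctr[2] > grid[2] ||
        !m[ctr[1], ctr[2]])
      stop("hotspot center for class '", cls, "' lies outside the RoI mask",
           call. = FALSE)
    # the fixed profile radius must fit inside the RoI around the hotspot
    semi <- floor(0.45 * cfg$grid)
    if (cfg$profile_radius / pitch + max(abs(cfg$hotspot_offset[[cls]])) >
        min(semi))
      stop("grid too small: profile radius a does not fit inside the RoI",
           call. = FALSE)
  }
  cfg
}

#' Elliptical RoI mask of a phantom
#' @param cfg a [phantom_config()].
#' @return Logical matrix, `TRUE` inside the RoI.
#' @export
phantom_mask <- function(cfg) {
  h <- cfg$grid[1]; w <- cfg$grid[2]
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  sr <- 0.45 * h; sc <- 0.45 * w
  r <- matrix(seq_len(h), h, w)
  c2 <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - cr) / sr)^2 + ((c2 - cc) / sc)^2 <= 1
}

phantom_hotspot_center <- function(cfg, class) {
  ctr <- round((cfg$grid + 1) / 2)
  as.integer(ctr + cfg$hotspot_offset[[class]])
}

# Row-normalized Gaussian blur operator for one dimension; blur2d applies it
# separably. Edge rows renormalize over the in-range support.
blur_operator <- function(n, sigma) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  K / rowSums(K)
}

blur2d <- function(mat, sigma) {
  blur_operator(nrow(mat), sigma) %*% mat %*% t(blur_operator(ncol(mat), sigma))
}

# Smooth zero-mean unit-sd (within mask) random field; consumes the RNG stream.
heterogeneity_field <- function(cfg, mask) {
  f <- blur2d(matrix(stats::rnorm(prod(cfg$grid)), cfg$grid[1], cfg$grid[2]),
              cfg$heterogeneity_scale)
  v <- f[mask]
  (f - mean(v)) / stats::sd(v)
}

# Effective source intensity at time t (latent dynamics tied to rewarming).
phantom_q_at <- function(cfg, class, t, kin = NULL, q_scale = 1) {
  if (is.null(kin)) kin <- cfg$kinetics[[class]]
  q_scale * cfg$source[[class]]$q *
    (cfg$q_floor + (1 - cfg$q_floor) * (1 - exp(-t / kin$tau)))
}

#' Generate a single phantom frame
#'
#' Composes baseline rewarming, the hotspot bump, a (caller-supplied)
#' heterogeneity field and sensor noise into one thermogram. Noise draws
#' consume the current RNG stream; seed at the sequence level for
#' reproducibility.
#'
#' @param cfg a [phantom_config()].
#' @param class `"control"` or `"cancer"`.
#' @param t time since end of cold stress (s).
#' @param field heterogeneity field matrix (already scaled to unit sd) or
#'   `NULL` for none.
#' @param noise if `FALSE`, omit sensor noise (noiseless frame).
#' @param kin optional subject-specific [recovery_kinetics()] overriding the
#'   class kinetics.
#' @param q_scale multiplicative subject-specific source-intensity factor.
#' @return A `thermal_frame`: temperature matrix (deg C) with attributes
#'   `pitch` and `time`.
#' @export
generate_frame <- function(cfg, class, t, field = NULL, noise = TRUE,
                           kin = NULL, q_scale = 1) {
  stopifnot(inherits(cfg, "phantom_config"), t >= 0,
            class %in% c("control", "cancer"))
  h <- cfg$grid[1]; w <- cfg$grid[2]
  if (is.null(kin)) kin <- cfg$kinetics[[class]]
  base <- recovery_curve(t, kin)
  frame <- matrix(base, h, w)

  src <- cfg$source[[class]]
  qt <- phantom_q_at(cfg, class, t, kin = kin, q_scale = q_scale)
  if (qt > 0) {
    ctr <- phantom_hotspot_center(cfg, class)
    rr <- (matrix(seq_len(h), h, w) - ctr[1]) * cfg$pitch
    cc <- (matrix(seq_len(w), h, w, byrow = TRUE) - ctr[2]) * cfg$pitch
    dist <- sqrt(rr^2 + cc^2)
    # surface law with the instantaneous baseline as the surround temperature
    frame <- frame + qt / (4 * pi * cfg$env$h0 * (src$d^2 + dist^2))
  }
  if (!is.null(field)) {
    frame <- frame + cfg$heterogeneity_sd[[class]] * field
  }
  if (noise && cfg$noise_sd > 0) {
    frame <- frame + matrix(stats::rnorm(h * w, sd = cfg$noise_sd), h, w)
  }
  structure(frame, pitch = cfg$pitch, time = t, class = c("thermal_frame", "matrix"))
}

#' Generate a dynamic thermogram sequence for one subject
#'
#' Frames at `t = 0, dt, ..., (M-1) dt`. The heterogeneity field is drawn once
#' and held fixed across frames (spatial structure persists); sensor noise is
#' redrawn every frame. Bit-identical given the same seed.
#'
#' @param cfg a [phantom_config()].
#' @param class `"control"` or `"cancer"`.
#' @param seed integer seed for this subject.
#' @param subject subject identifier string.
#' @return A `thermogram_sequence`: list with `frames` (list of matrices),
#'   `times`, `mask`, `label`, `subject`, `pitch`, `seed`.
#' @export
generate_sequence <- function(cfg, class, seed = 1L, subject = "s1") {
  stopifnot(inherits(cfg, "phantom_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  mask <- phantom_mask(cfg)
  # per-subject biology: warmth level, recovery amplitude, time constant, and
  # source strength all vary across subjects within a class
  ssd <- cfg$subject_sd
  lev <- stats::rnorm(1, 0, ssd[["level"]])
  amp <- stats::rnorm(1, 0, ssd[["amplitude"]])
  kin0 <- cfg$kinetics[[class]]
  kin <- recovery_kinetics(kin0$T0 + lev,
                           max(kin0$Tinf + lev + amp, kin0$T0 + lev),
                           kin0$tau * exp(stats::rnorm(1, 0, ssd[["tau_lnsd"]])))
  q_scale <- exp(stats::rnorm(1, 0, ssd[["q_lnsd"]]))
  field <- heterogeneity_field(cfg, mask)
  times <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval
  frames <- lapply(times, function(t)
    generate_frame(cfg, class, t, field, kin = kin, q_scale = q_scale))
  structure(list(frames = frames, times = times, mask = mask, label = class,
                 subject = subject, pitch = cfg$pitch, seed = seed,
                 kinetics = kin),
            class = "thermogram_sequence")
}

#' Generate a balanced phantom cohort
#'
#' `n_per_class` cancer and `n_per_class` control sequences with per-subject
#' seeds derived from the master seed; subject order is shuffled
#' deterministically.
#'
#' @param cfg a [phantom_config()].
#' @return A `thermogram_cohort`: list of [generate_sequence()] results.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  classes <- rep(c("control", "cancer"), each = cfg$n_per_class)
  ids <- sprintf("%s%02d", ifelse(classes == "cancer", "ca", "co"),
                 c(seq_len(cfg$n_per_class), seq_len(cfg$n_per_class)))
  seeds <- (as.numeric(cfg$seed) * 7919 + seq_along(classes) * 104729) %%
    2147483647
  seqs <- mapply(function(cl, sd, id) generate_sequence(cfg, cl, as.integer(sd), id),
                 classes, seeds, ids, SIMPLIFY = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  seqs <- seqs[sample(length(seqs))]
  names(seqs) <- vapply(seqs, `[[`, "", "subject")
  structure(seqs, class = "thermogram_cohort")
}

#' Expected noiseless frame statistics of the phantom
#'
#' Mask mean and maximum of a frame generated with noise and heterogeneity
#' switched off; used as the generator's own oracle for cohort-level checks.
#'
#' @param cfg a [phantom_config()].
#' @param class class label.
#' @param t frame time (s).
#' @return Named numeric `c(mean, max)`.
#' @export
expected_frame_stats <- function(cfg, class, t) {
  f <- generate_frame(cfg, class, t, field = NULL, noise = FALSE)
  m <- phantom_mask(cfg)
  c(mean = mean(f[m]), max = max(f[m]))
}
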