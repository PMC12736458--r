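# Hotspot localization, radial profiling, and the D-I-R inversion.

test_that("hotspot localization is exact and tie-broken row-major", {
  fr <- analytic_frame()
  mask <- matrix(TRUE, nrow(fr), ncol(fr))
  expect_identical(locate_hotspot(unclass(fr), mask)$center, c(26L, 26L))
  # constant frame: first masked pixel in row-major order
  const <- matrix(30, 4, 4)
  m <- matrix(FALSE, 4, 4); m[3, 2] <- m[2, 4] <- TRUE
  hs <- locate_hotspot(const, m)
  expect_identical(hs$center, c(2L, 4L))  # row-major (2,4) before (3,2)
  expect_identical(hs$Tmax, 30)
  # two equal maxima: deterministic row-major winner
  two <- matrix(0, 3, 3); two[2, 3] <- two[3, 1] <- 5
  expect_identical(locate_hotspot(two, matrix(TRUE, 3, 3))$center, c(2L, 3L))
  expect_error(locate_hotspot(const, matrix(FALSE, 4, 4)), "empty")
})

test_that("annulus sampling reproduces the closed-form profile to half-pixel accuracy", {
  fr <- analytic_frame(q = 0.132, d = 0.02, Te = 30)
  mask <- matrix(TRUE, nrow(fr), ncol(fr))
  prof <- sample_profile(fr, mask, c(26L, 26L), a = 0.0168, pitch = 0.001,
                         Te = 30)
  analytic <- surface_temperature(0.0168, heat_source(0.132, 0.02),
                                  thermal_environment(Te = 30))
  # annulus width is one pixel; curvature error stays below a half-pixel step
  slope_halfpx <- abs(analytic -
    surface_temperature(0.0168 + 5e-4, heat_source(0.132, 0.02),
                        thermal_environment(Te = 30)))
  expect_equal(prof$Ta, analytic, tolerance = slope_halfpx / analytic)
  expect_error(sample_profile(fr, mask, c(26L, 26L), a = 0.2, pitch = 0.001),
               "max achievable radius")
})

test_that("line-mode sampling averages the two horizontal samples", {
  fr <- analytic_frame()
  mask <- matrix(TRUE, nrow(fr), ncol(fr))
  prof <- sample_profile(fr, mask, c(26L, 26L), a = 0.017, pitch = 0.001,
                         mode = "line", Te = 30)
  expect_equal(prof$Ta, (fr[26, 26 - 17] + fr[26, 26 + 17]) / 2)
})

test_that("D-I-R inversion is algebraically exact on continuous profiles", {
  env <- thermal_environment(Te = 30)
  a <- 0.0168
  for (q in c(0.01, 0.132, 0.5, 1)) {
    for (d in c(0.005, 0.02, 0.035, 0.05)) {
      src <- heat_source(q, d)
      prof <- radial_profile(Tmax = surface_temperature(0, src, env),
                             Ta = surface_temperature(a, src, env),
                             Te = 30, a = a)
      expect_equal(estimate_depth(prof), d, tolerance = 1e-12)
      expect_equal(estimate_intensity(prof, env), q, tolerance = 1e-12)
    }
  }
  # unit-ratio case: (Ta - Te) = (Tmax - Ta) gives d = a
  prof <- radial_profile(Tmax = 34, Ta = 32, Te = 30, a = a)
  expect_equal(estimate_depth(prof), a)
})

test_that("inverting a finite-radius profile recovers the effective depth d + R", {
  env <- thermal_environment(Te = 30)
  src <- heat_source(0.2, d = 0.015, R = 0.01)
  a <- 0.0168
  prof <- radial_profile(
    Tmax = surface_temperature(0, src, env, use_radius = TRUE),
    Ta = surface_temperature(a, src, env, use_radius = TRUE),
    Te = 30, a = a)
  expect_equal(estimate_depth(prof), 0.025, tolerance = 1e-12)
})

test_that("degenerate profiles raise a typed condition", {
  expect_error(estimate_depth(radial_profile(32, 32, 30)),
               class = "thermoseries_degenerate")
  expect_error(estimate_intensity(radial_profile(33, 30, 30)),
               class = "thermoseries_degenerate")
})

test_that("equivalent radius follows the cube-root law", {
  env <- thermal_environment()
  expect_identical(estimate_radius(0, env), 0)
  expect_equal(estimate_radius(418.6, env), 1)
  expect_equal(estimate_radius(0.132, env), 0.0680, tolerance = 1e-3)
  expect_error(estimate_radius(-1, env), "non-negative")
})

test_that("frame descriptors recover the generator's source on noiseless phantoms", {
  cfg <- phantom_config()
  fr <- generate_frame(cfg, "cancer", t = 150, field = NULL, noise = FALSE)
  mask <- phantom_mask(cfg)
  # the oracle knows the true surround temperature (the instantaneous
  # baseline); residual error is the half-pixel annulus discretization
  base <- recovery_curve(150, cfg$kinetics$cancer)
  fd <- frame_descriptors(fr, mask, cfg$env, Te = base)
  qt <- thermoseries:::phantom_q_at(cfg, "cancer", 150)
  expect_equal(fd$d, cfg$source$cancer$d, tolerance = 0.02)
  expect_equal(fd$q, qt, tolerance = 0.10)
  expect_false(fd$degenerate)
  expect_identical(fd$Tmax, max(fr[mask]))
  expect_equal(fd$Tmean, mean(fr[mask]))
  expect_equal(fd$sigma, sd(fr[mask]))
})

test_that("constant frames yield degenerate q/d but valid temperature stats", {
  fr <- structure(matrix(30, 40, 40), pitch = 0.001,
                  class = c("thermal_frame", "matrix"))
  mask <- matrix(TRUE, 40, 40)
  fd <- frame_descriptors(fr, mask)
  expect_identical(fd$Tmax, 30)
  expect_identical(fd$Tmean, 30)
  expect_identical(fd$sigma, 0)
  expect_true(fd$degenerate)
  expect_true(is.na(fd$q) && is.na(fd$d))
})

test_that("intensity estimate is robust in the median under pixel noise", {
  env <- thermal_environment(Te = 30)
  clean <- unclass(analytic_frame(q = 0.132, d = 0.02, Te = 30))
  mask <- matrix(TRUE, nrow(clean), ncol(clean))
  set.seed(7)
  qs <- replicate(500, {
    fr <- clean + matrix(rnorm(length(clean), sd = 0.05), nrow(clean))
    hs <- locate_hotspot(fr, mask)
    prof <- sample_profile(fr, mask, hs$center, a = 0.0168, pitch = 0.001,
                           Te = 30)
    tryCatch(estimate_intensity(prof, env), error = function(e) NA_real_)
  })
  expect_lt(abs(median(qs, na.rm = TRUE) - 0.132), 0.1 * 0.132)
})

test_that("descriptors q and d are invariant to a constant frame shift", {
  cfg <- phantom_config()
  s <- generate_sequence(cfg, "cancer", seed = 21)
  fr <- s$frames[[5]]
  fd1 <- frame_descriptors(fr, s$mask, cfg$env)
  fd2 <- frame_descriptors(fr + 2.5, s$mask, cfg$env)
  expect_equal(fd2$q, fd1$q, tolerance = 1e-10)
  expect_equal(fd2$d, fd1$d, tolerance = 1e-10)
  expect_equal(fd2$Tmean, fd1$Tmean + 2.5)
})

test_that("sequence descriptors carry degenerate frames forward with a flag", {
  # construct a sequence whose middle frame is constant (degenerate)
  cfg <- phantom_config(noise_sd = 0)
  s <- generate_sequence(cfg, "cancer", seed = 3)
  s$frames[[3]] <- structure(matrix(33, cfg$grid[1], cfg$grid[2]),
                             pitch = cfg$pitch,
                             class = c("thermal_frame", "matrix"))
  df <- sequence_descriptors(s, cfg$env)
  expect_identical(nrow(df), 20L)
  expect_true(df$degenerate[3])
  expect_identical(df$q[3], df$q[2])
  expect_identical(df$d[3], df$d[2])
  expect_false(anyNA(df[c("q", "d", "R")]))
})
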