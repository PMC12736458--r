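# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Small phantom cohort tensor (descriptors already extracted).
small_cohort_tensor <- function(n_per_class = 8, seed = 11) {
  key <- sprintf("tensor_%d_%d", n_per_class, seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- phantom_config(n_per_class = n_per_class, seed = seed)
  tensor <- assemble_tensor(cohort_descriptors(generate_cohort(cfg)))
  .fixture_cache[[key]] <- tensor
  tensor
}

# Frame built pixel-by-pixel from the point-source surface law (no noise,
# no heterogeneity), hotspot at the grid center.
analytic_frame <- function(q = 0.132, d = 0.02, Te = 30, n = 51,
                           pitch = 0.001, use_radius = FALSE, R = 0) {
  env <- thermal_environment(Te = Te)
  src <- heat_source(q, d, R)
  ctr <- (n + 1) / 2
  rr <- (matrix(seq_len(n), n, n) - ctr) * pitch
  cc <- (matrix(seq_len(n), n, n, byrow = TRUE) - ctr) * pitch
  a <- sqrt(rr^2 + cc^2)
  fr <- matrix(surface_temperature(as.vector(a), src, env,
                                   use_radius = use_radius), n, n)
  structure(fr, pitch = pitch, class = c("thermal_frame", "matrix"))
}

# Trainer-layout weights assembled from a reference gate-wise weight list.
trainer_weights_from_ref <- function(w) {
  list(W = cbind(t(w$Wf), t(w$Wi), t(w$Wc), t(w$Wo)),
       b = c(w$bf, w$bi, w$bc, w$bo))
}

random_ref_weights <- function(H, D, sd = 0.4) {
  list(Wf = matrix(rnorm(H * (H + D), sd = sd), H),
       Wi = matrix(rnorm(H * (H + D), sd = sd), H),
       Wc = matrix(rnorm(H * (H + D), sd = sd), H),
       Wo = matrix(rnorm(H * (H + D), sd = sd), H),
       bf = rnorm(H), bi = rnorm(H), bc = rnorm(H), bo = rnorm(H))
}

# A trivially separable cohort tensor: class-shifted smooth series.
separable_tensor <- function(n_per_class = 10, M = 20, V = 5, gap = 3,
                             seed = 1) {
  set.seed(seed)
  N <- 2 * n_per_class
  labels <- rep(c("control", "cancer"), each = n_per_class)
  values <- array(rnorm(N * M * V, sd = 0.3), c(N, M, V))
  values[labels == "cancer", , ] <- values[labels == "cancer", , ] + gap
  dimnames(values) <- list(paste0("s", 1:N), NULL,
                           c("Tmax", "Tmean", "sigma", "q", "d")[1:V])
  thermoseries:::new_cohort_tensor(values, labels, paste0("s", 1:N),
                                   dimnames(values)[[3]])
}
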