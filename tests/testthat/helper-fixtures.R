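# Shared fixtures: all data are generated in code at test time.

# Small-mode cohort for fast pipeline tests: 8 + 8 patients, 32 px images.
small_cohort <- function(seed = 1L, n = c(8L, 8L), slices = c(1L, 2L), ...) {
  generate_cohort(synth_config(n, slices_per_patient_range = slices,
                               image_size = 32L, seed = seed, ...))
}

# Tiny MA configuration whose gradients are cheap to finite-difference.
tiny_ma_config <- function(batchnorm = TRUE) {
  ma_config(8L, 4L, cbam_ratio = 2L, spatial_kernel = 3L,
            batchnorm = batchnorm)
}

# Central-difference gradient of f at x (numeric array).
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Patient-level table: every slice of a patient must carry one split.
expect_no_patient_leakage <- function(cohort, col = "split") {
  per_patient <- tapply(cohort[[col]], cohort$patient_id,
                        function(v) length(unique(v)))
  expect_true(all(per_patient == 1L))
}
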