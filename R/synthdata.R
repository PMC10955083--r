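# Synthetic paired-modality cohort generator. Each patient contributes 1-5
# paired slices; the class signal is split complementarily across the two
# modalities: modality A carries an oriented sinusoidal texture inside the
# lesion disk, modality B a contrast offset on the rim annulus. Both cue
# templates are L2-normalised, so the matched-filter deflection of modality
# m is d_m = effect_m * cue_scale / noise_sigma independent of image size,
# and the Bayes-optimal accuracy of any cue subset is available by numeric
# integration of the induced one-dimensional Gaussian statistic.

#' Synthetic cohort configuration
#'
#' @param n_patients_per_class Either a single count (split between the two
#'   classes by `class_imbalance`) or a length-2 integer vector
#'   `c(n_high, n_low)`. The default mirrors a 76 + 62 cohort.
#' @param slices_per_patient_range Integer interval, paired slices per
#'   patient (default 1-5).
#' @param image_size Square image side in pixels before any cropping.
#' @param effect_a,effect_b Unitless strengths of the class cue carried by
#'   modality A (lesion texture) and modality B (rim contrast).
#' @param noise_sigma Gray-level standard deviation of the i.i.d. Gaussian
#'   pixel noise; must be positive.
#' @param class_imbalance Fraction of high-grade patients when
#'   `n_patients_per_class` is a single count.
#' @param cue_scale L2 norms of the unit-effect cue templates in gray
#'   levels, `c(a, b)` (recycled if length 1). The texture cue (A) needs a
#'   larger norm than the enhancement cue (B) to reach similar learnability:
#'   after global pooling a network can read the texture only through
#'   rectified-filter energy, a quadratic statistic that requires per-pixel
#'   contrast on the order of the noise, whereas the mean-enhancement cue is
#'   read linearly. The matched-filter (Bayes) deflection of modality m
#'   stays `effect_m * cue_scale_m / noise_sigma`.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical cohorts.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_patients_per_class = 69L,
                         slices_per_patient_range = c(1L, 5L),
                         image_size = 64L,
                         effect_a = 1, effect_b = 1,
                         noise_sigma = 0.05,
                         class_imbalance = 0.551,
                         cue_scale = c(1.2, 0.125),
                         seed = 1L) {
  if (length(n_patients_per_class) == 2L) {
    n_high <- as.integer(n_patients_per_class[1])
    n_low <- as.integer(n_patients_per_class[2])
  } else {
    n <- as.integer(n_patients_per_class)
    n_high <- as.integer(round(2 * n * class_imbalance))
    n_low <- 2L * n - n_high
  }
  if (n_high <= 0L || n_low <= 0L) stop("patient counts must be positive")
  r <- as.integer(slices_per_patient_range)
  if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) {
    stop("degenerate slices_per_patient_range")
  }
  if (effect_a < 0 || effect_b < 0) stop("effects must be nonnegative")
  if (noise_sigma <= 0) stop("noise_sigma must be positive")
  cue_scale <- rep_len(cue_scale, 2L)
  structure(list(n_high = n_high, n_low = n_low,
                 slices_per_patient_range = r,
                 image_size = as.integer(image_size),
                 effect_a = effect_a, effect_b = effect_b,
                 noise_sigma = noise_sigma,
                 class_imbalance = n_high / (n_high + n_low),
                 cue_scale = cue_scale,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_high, "+", x$n_low, " patients, ",
      x$slices_per_patient_range[1], "-", x$slices_per_patient_range[2],
      " slices, ", x$image_size, "px, effects (",
      x$effect_a, ", ", x$effect_b, "), sigma ", x$noise_sigma, "\n", sep = "")
  invisible(x)
}

#' Read / write a synthetic configuration as YAML
#' @export
synth_config_from_yaml <- function(path) {
  do.call(synth_config, yaml::read_yaml(path))
}

# Deterministic scene shared by both modalities plus the two normalised cue
# templates. The lesion disk (radius size/4) is part of the scene but is
# class-uninformative; the class cues are position-free statistics, chosen
# so that a network whose features are global averages of rectified filter
# responses can realise (nearly) the matched-filter deflection:
#   modality A - 45-degree sinusoidal texture inside the lesion disk
#                (a structural-sequence cue, read out as rectified-filter
#                energy after pooling);
#   modality B - diffuse intensity enhancement over the whole field
#                (a contrast-enhancement cue, read out as the global mean).
# Both templates are L2-normalised and mutually orthogonal, so the
# matched-filter deflection of modality m is
# d_m = effect_m * cue_scale_m / noise_sigma and the joint deflection is
# sqrt(d_a^2 + d_b^2) (conditional independence given the class).
synth_templates <- function(size) {
  c0 <- (size + 1) / 2
  xx <- matrix(seq_len(size), size, size)
  yy <- t(xx)
  rr <- sqrt((xx - c0)^2 + (yy - c0)^2)
  r0 <- size / 4
  lesion <- rr <= r0
  wavelength <- size / 8
  phase <- 2 * pi * ((xx - c0) + (yy - c0)) / (sqrt(2) * wavelength)
  ta <- sin(phase) * lesion
  ta <- ta - mean(ta)                      # orthogonal to the flat template
  ta <- ta / sqrt(sum(ta^2))
  tb <- matrix(1, size, size)
  tb <- tb / sqrt(sum(tb))
  base <- 0.45 + 0.08 * lesion + 0.03 * (xx - 1) / (size - 1)
  list(base = base, template_a = ta, template_b = tb, lesion = lesion)
}

#' Generate a synthetic paired-modality cohort
#'
#' Draws `1`-`5` paired slices per patient (uniformly on the configured
#' range). High-grade slices carry the modality-A texture cue and the
#' modality-B rim cue at the configured effect strengths; low-grade slices
#' carry neither. Pixel noise is i.i.d. Gaussian and independent across
#' slices and modalities, so the two cues are conditionally independent
#' given the class and the Bayes-optimal joint classifier strictly beats
#' each marginal one whenever both effects are positive (see
#' [bayes_oracle()]).
#'
#' @param config A [synth_config()].
#' @param dir Optional directory; when given, images are written as PNG and
#'   the manifest carries their paths.
#' @return A tibble with one row per paired slice: `patient_id`, `label`
#'   (1 = high grade), `slice`, list-columns `image_a`/`image_b` (matrices in
#'   `[0, 1]`), `path_a`/`path_b` (when written), `split` (`NA`, see
#'   [stratified_patient_split()]) and `is_augmented`.
#' @examples
#' cohort <- generate_cohort(synth_config(c(4, 4), image_size = 32, seed = 1))
#' dplyr::count(cohort, label)
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  tpl <- synth_templates(config$image_size)
  n_all <- config$n_high + config$n_low
  labels <- rep(c(1L, 0L), c(config$n_high, config$n_low))
  ids <- sprintf("P%03d", seq_len(n_all))
  rng <- config$slices_per_patient_range
  n_slices <- sample(seq(rng[1], rng[2]), n_all, replace = TRUE)
  rows <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    y <- labels[i]
    sl <- lapply(seq_len(n_slices[i]), function(s) {
      a <- tpl$base + config$effect_a * y * config$cue_scale[1] * tpl$template_a +
        matrix(stats::rnorm(config$image_size^2, sd = config$noise_sigma),
               config$image_size)
      b <- tpl$base + config$effect_b * y * config$cue_scale[2] * tpl$template_b +
        matrix(stats::rnorm(config$image_size^2, sd = config$noise_sigma),
               config$image_size)
      list(a = pmin(pmax(a, 0), 1), b = pmin(pmax(b, 0), 1))
    })
    rows[[i]] <- tibble::tibble(
      patient_id = ids[i], label = y, slice = seq_len(n_slices[i]),
      image_a = lapply(sl, `[[`, "a"), image_b = lapply(sl, `[[`, "b"))
  }
  cohort <- dplyr::bind_rows(rows)
  cohort$split <- NA_character_
  cohort$is_augmented <- FALSE
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cohort$path_a <- file.path(dir, sprintf("%s_s%02d_A.png", cohort$patient_id, cohort$slice))
    cohort$path_b <- file.path(dir, sprintf("%s_s%02d_B.png", cohort$patient_id, cohort$slice))
    purrr::pwalk(list(cohort$image_a, cohort$path_a), function(im, p) png::writePNG(im, p))
    purrr::pwalk(list(cohort$image_b, cohort$path_b), function(im, p) png::writePNG(im, p))
  }
  cohort
}

#' Matched-filter cue scores of a cohort
#'
#' Projects each slice onto the generator's (known, normalised) cue
#' templates. Under the cue model the standardised score of modality m is
#' N(0, 1) for low grade and N(d_m, 1) for high grade, with
#' `d_m = effect_m * cue_scale / noise_sigma`; `score_joint` is the
#' likelihood-ratio combination of the two.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param config The configuration the cohort was generated with.
#' @return The cohort with `score_a`, `score_b`, `score_joint` columns.
#' @export
cue_scores <- function(cohort, config) {
  tpl <- synth_templates(config$image_size)
  sig <- config$noise_sigma
  za <- purrr::map_dbl(cohort$image_a, ~ sum(tpl$template_a * (.x - tpl$base)) / sig)
  zb <- purrr::map_dbl(cohort$image_b, ~ sum(tpl$template_b * (.x - tpl$base)) / sig)
  d <- cue_deflections(config)
  dplyr::mutate(cohort, score_a = za, score_b = zb,
                score_joint = d[["a"]] * za + d[["b"]] * zb)
}

cue_deflections <- function(config) {
  c(a = config$effect_a * config$cue_scale[1] / config$noise_sigma,
    b = config$effect_b * config$cue_scale[2] / config$noise_sigma)
}

#' Bayes oracle for the synthetic cue model
#'
#' For each cue subset (modality A alone, B alone, both) the slice label
#' posterior depends on a one-dimensional Gaussian statistic with unit
#' variance and class separation `D` (`d_a`, `d_b`, or
#' `sqrt(d_a^2 + d_b^2)` for the conditionally independent joint cue). The
#' Bayes accuracy under the configured class prior is computed by numeric
#' integration of `max(pi1 * phi(t - D), pi0 * phi(t))`, and the AUC of the
#' optimal score by integration of the rank statistic. Both quantities
#' upper-bound any classifier trained on the generated images.
#'
#' @param config A [synth_config()].
#' @return A one-row tibble with deflections, Bayes accuracies and AUCs for
#'   the marginal and joint cues.
#' @export
bayes_oracle <- function(config) {
  d <- cue_deflections(config)
  pi1 <- config$class_imbalance
  pi0 <- 1 - pi1
  acc <- function(D) {
    if (D == 0) return(max(pi0, pi1))
    stats::integrate(function(t) pmax(pi1 * stats::dnorm(t, D, 1),
                                      pi0 * stats::dnorm(t, 0, 1)),
                     lower = -Inf, upper = Inf, rel.tol = 1e-10)$value
  }
  auc <- function(D) {
    if (D == 0) return(0.5)
    stats::integrate(function(t) stats::dnorm(t, D, 1) * stats::pnorm(t),
                     lower = -Inf, upper = Inf, rel.tol = 1e-10)$value
  }
  Dj <- sqrt(sum(d^2))
  tibble::tibble(
    deflection_a = d[["a"]], deflection_b = d[["b"]], deflection_joint = Dj,
    accuracy_a = acc(d[["a"]]), accuracy_b = acc(d[["b"]]), accuracy_joint = acc(Dj),
    auc_a = auc(d[["a"]]), auc_b = auc(d[["b"]]), auc_joint = auc(Dj))
}

#' Long-format image manifest
#'
#' Converts a slice-level cohort tibble to the on-disk manifest schema: one
#' row per image with columns `patient_id`, `label`, `modality`, `path`,
#' `split`, `is_augmented`.
#' @export
cohort_manifest <- function(cohort) {
  has_paths <- all(c("path_a", "path_b") %in% names(cohort))
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, dplyr::any_of(c("patient_id", "label", "slice",
                                          "split", "is_augmented",
                                          "path_a", "path_b"))),
    cols = dplyr::any_of(c("path_a", "path_b")),
    names_to = "modality", values_to = "path", names_prefix = "path_")
  if (!has_paths) long$path <- NA_character_
  long$modality <- toupper(long$modality)
  dplyr::select(long, "patient_id", "label", "modality", "path", "split",
                "is_augmented", "slice")
}

#' Reference cohort manifest
#'
#' Emits the slice-count manifest of the 138-patient clinical bladder-cancer
#' cohort that the synthetic generator emulates: 60/8/8 high-grade and
#' 50/6/6 low-grade patients across train/val/test, with 155/19/19 and
#' 99/12/12 original paired slices (316 in total) and 743/94/94 and
#' 665/82/82 augmented ones (1760 in total). Patient ids are synthetic;
#' slices are distributed as evenly as possible (1-5 per patient), and every
#' patient appears in exactly one split.
#'
#' @return A tibble with one row per paired slice: `patient_id`, `label`,
#'   `split`, `slice`, `is_augmented`.
#' @export
reference_split_manifest <- function() {
  layout <- tibble::tibble(
    label = rep(c(1L, 0L), each = 3L),
    split = rep(c("train", "val", "test"), 2L),
    patients = c(60L, 8L, 8L, 50L, 6L, 6L),
    original = c(155L, 19L, 19L, 99L, 12L, 12L),
    augmented = c(743L, 94L, 94L, 665L, 82L, 82L))
  counter <- new.env()
  counter$i <- 0L
  one_group <- function(label, split, patients, original, augmented) {
    ids <- sprintf("R%03d", counter$i + seq_len(patients))
    counter$i <- counter$i + patients
    spread <- function(total) {
      per <- rep(total %/% patients, patients)
      extra <- total %% patients
      if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
      per
    }
    orig <- spread(original)
    aug <- spread(augmented)
    dplyr::bind_rows(
      tibble::tibble(patient_id = rep(ids, orig), label = label, split = split,
                     slice = unlist(lapply(orig, seq_len)), is_augmented = FALSE),
      tibble::tibble(patient_id = rep(ids, aug), label = label, split = split,
                     slice = unlist(lapply(aug, seq_len)), is_augmented = TRUE))
  }
  purrr::pmap_dfr(layout, one_group)
}
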