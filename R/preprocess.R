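# Preprocessing: centre crop + size standardisation, the four training
# augmentations (vertical flip, horizontal flip, brightness, shear),
# patient-level stratified 8:1:1 splitting and the patient-level k-fold
# splitter. All split assignment is by patient so no patient's slices ever
# straddle two splits.

#' Centre crop and standardise an image
#'
#' Extracts the centre square of side `min(H, W)` and resizes it to
#' `target x target` with bilinear interpolation; grayscale input is
#' replicated to three channels.
#'
#' @param image A numeric matrix `[H, W]` or array `[H, W, C]` in `[0, 1]`.
#' @param target Output side in pixels (default 224).
#' @param channels Output channel count (default 3).
#' @return Array `[target, target, channels]`.
#' @examples
#' img <- matrix(runif(300 * 240), 300, 240)
#' dim(center_crop_standardize(img))  # 224 224 3
#' @export
center_crop_standardize <- function(image, target = 224L, channels = 3L) {
  d <- dim(image)
  if (is.null(d) || any(d[1:2] < 1L)) stop("empty image")
  H <- d[1]; W <- d[2]
  side <- min(H, W)
  r0 <- (H - side) %/% 2L
  c0 <- (W - side) %/% 2L
  crop_one <- function(m) m[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
  resize_one <- function(m) {
    if (side == target) m else EBImage::resize(m, w = target, h = target)
  }
  if (length(d) == 2L) {
    plane <- resize_one(crop_one(image))
    out <- array(plane, c(target, target, channels))
  } else {
    out <- array(0, c(target, target, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- resize_one(crop_one(image[, , c]))
    if (d[3] == 1L && channels > 1L) out <- array(out, c(target, target, channels))
  }
  out
}

#' Randomly augment an image
#'
#' Applies, with independent draws from the seeded stream, a vertical flip
#' (probability `flip_prob`), a horizontal flip (`flip_prob`), a brightness
#' scaling (uniform on `brightness_range`, clipped to `[0, 1]`) and a shear
#' ("miscut") by an angle uniform on `shear_range` degrees. Shape and label
#' semantics are unchanged.
#'
#' @param image Matrix or `[H, W, C]` array in `[0, 1]`.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @export
augment_image <- function(image, seed = NULL, flip_prob = 0.5,
                          brightness_range = c(0.8, 1.2),
                          shear_range = c(-10, 10)) {
  if (!is.null(seed)) set.seed(seed)
  vflip <- stats::runif(1) < flip_prob
  hflip <- stats::runif(1) < flip_prob
  bright <- stats::runif(1, brightness_range[1], brightness_range[2])
  shear_deg <- stats::runif(1, shear_range[1], shear_range[2])
  apply_plane <- function(m) {
    if (vflip) m <- m[nrow(m):1, , drop = FALSE]
    if (hflip) m <- m[, ncol(m):1, drop = FALSE]
    m <- pmin(pmax(m * bright, 0), 1)
    if (abs(shear_deg) > 1e-8) {
      t <- tan(shear_deg * pi / 180)
      tr <- matrix(c(1, t, -t * nrow(m) / 2, 0, 1, 0), 3, 2)
      m <- EBImage::affine(m, tr, filter = "bilinear", output.dim = dim(m))
      m <- pmin(pmax(m, 0), 1)
    }
    m
  }
  d <- dim(image)
  if (length(d) == 2L) return(apply_plane(image))
  out <- image
  for (c in seq_len(d[3])) out[, , c] <- apply_plane(image[, , c])
  out
}

#' Materialise augmented copies of a cohort
#'
#' Appends `times` augmented versions of every slice (both modalities get
#' the same draw of flips/brightness/shear), flagged `is_augmented = TRUE`.
#' `times` may be a named vector (names `"0"`, `"1"`) to expand the two
#' classes unequally, e.g. for class balancing.
#' @param cohort A cohort tibble with `image_a`/`image_b` list-columns.
#' @export
augment_cohort <- function(cohort, times = 4L, seed = 1L) {
  set.seed(seed)
  times_for <- function(label) {
    if (!is.null(names(times))) as.integer(times[[as.character(label)]])
    else as.integer(times)
  }
  extra <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    nt <- times_for(row$label)
    if (nt == 0L) return(NULL)
    purrr::map_dfr(seq_len(nt), function(j) {
      draw <- stats::runif(1, 0, .Machine$integer.max)
      row2 <- row
      row2$image_a <- list(augment_image(row$image_a[[1]], seed = draw))
      row2$image_b <- list(augment_image(row$image_b[[1]], seed = draw))
      row2$is_augmented <- TRUE
      row2
    })
  })
  dplyr::bind_rows(cohort, extra)
}

split_sizes <- function(n, ratios = c(8, 1, 1)) {
  R <- sum(ratios)
  n_val <- round(n * ratios[2] / R)
  n_test <- round(n * ratios[3] / R)
  c(train = n - n_val - n_test, val = n_val, test = n_test)
}

#' Patient-level stratified train/val/test split
#'
#' Within each class, `round(n * 1/10)` patients go to validation and to
#' test and the remainder to training (for the default 8:1:1 ratios); all of
#' a patient's slices follow the patient. For a 76 + 62 cohort this yields
#' 110/14/14 patients with 60/8/8 high grade and 50/6/6 low grade.
#'
#' @param cohort A tibble with `patient_id` and `label` columns (slice- or
#'   patient-level).
#' @param ratios Length-3 positive weights for train/val/test.
#' @param seed Seed for the randomised membership.
#' @return The input tibble with its `split` column filled; patient-level
#'   counts are attached as attribute `"split_counts"`.
#' @export
stratified_patient_split <- function(cohort, ratios = c(8, 1, 1), seed = 1L) {
  patients <- dplyr::distinct(cohort, .data$patient_id, .data$label)
  if (any(duplicated(patients$patient_id))) {
    stop("a patient carries more than one label")
  }
  set.seed(seed)
  assign_class <- function(df) {
    n <- nrow(df)
    if (n < 3L) stop("class ", df$label[1], " has fewer than 3 patients")
    sz <- split_sizes(n, ratios)
    lab <- sample(rep(c("train", "val", "test"), sz))
    df$split <- lab
    df
  }
  patients <- dplyr::group_split(patients, .data$label) |>
    purrr::map_dfr(assign_class)
  out <- dplyr::select(cohort, -dplyr::any_of("split")) |>
    dplyr::left_join(dplyr::select(patients, "patient_id", "split"),
                     by = "patient_id")
  counts <- dplyr::count(patients, .data$label, .data$split)
  attr(out, "split_counts") <- counts
  out
}

#' Patient-level k-fold assignment
#'
#' Assigns each patient to one of `k` folds (sizes differing by at most one,
#' stratified by class). Use [fold_split()] to expand fold `i` into
#' train/val/test: subset `i` is the test set, the next subset the
#' validation set and the remaining `k - 2` the training set, so each
#' patient is tested exactly once across the `k` folds.
#'
#' @param cohort Tibble with `patient_id` and `label`.
#' @param k Number of folds (default 10).
#' @export
kfold_split <- function(cohort, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  patients <- dplyr::distinct(cohort, .data$patient_id, .data$label)
  if (nrow(patients) < k) stop("fewer patients than folds")
  set.seed(seed)
  assign_class <- function(df) {
    n <- nrow(df)
    df$fold <- sample(rep_len(seq_len(k), n))
    df
  }
  patients <- dplyr::group_split(patients, .data$label) |>
    purrr::map_dfr(assign_class)
  dplyr::select(cohort, -dplyr::any_of("fold")) |>
    dplyr::left_join(dplyr::select(patients, "patient_id", "fold"),
                     by = "patient_id")
}

#' @rdname kfold_split
#' @param fold Which fold (1..k) plays the test set.
#' @export
fold_split <- function(cohort, fold, k = max(cohort$fold)) {
  if (!"fold" %in% names(cohort)) stop("run kfold_split() first")
  val_fold <- fold %% k + 1L
  dplyr::mutate(cohort, split = dplyr::case_when(
    .data$fold == !!fold ~ "test",
    .data$fold == !!val_fold ~ "val",
    TRUE ~ "train"))
}

#' Stack cohort images into network-ready batches
#'
#' Converts the list-column images of a cohort slice subset into a
#' `[B, H, W, C]` array pair in `[0, 1]` with grayscale replicated to
#' `channels`.
#' @param cohort Cohort tibble rows to stack.
#' @param target Optional side length; images are centre-cropped and
#'   resized when it differs from their native size.
#' @export
cohort_batch <- function(cohort, target = NULL, channels = 3L) {
  stack <- function(images) {
    first <- images[[1]]
    side <- if (is.null(target)) min(dim(first)[1:2]) else as.integer(target)
    arrs <- lapply(images, function(m) {
      if (!is.null(target) || !is.matrix(m)) {
        center_crop_standardize(m, side, channels)
      } else array(m, c(dim(m), channels))
    })
    out <- array(0, c(length(arrs), side, side, channels))
    for (i in seq_along(arrs)) out[i, , , ] <- arrs[[i]]
    out
  }
  list(x1 = stack(cohort$image_a), x2 = stack(cohort$image_b),
       labels = cohort$label)
}
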