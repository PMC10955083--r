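# Manifest and image I/O: manifests are CSV with the shared schema
# (patient_id, label, modality, path, split, is_augmented), images PNG,
# configurations YAML.

#' Write / read a cohort manifest CSV
#' @param cohort Cohort tibble (slice-level); converted with
#'   [cohort_manifest()].
#' @param path CSV destination.
#' @export
write_manifest <- function(cohort, path) {
  utils::write.csv(cohort_manifest(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Load a cohort (with images) from a manifest
#'
#' Reads the long-format manifest and the PNG images it references back
#' into the slice-level tibble used by the training functions.
#' @param path Manifest CSV written by [write_manifest()].
#' @export
cohort_from_manifest <- function(path) {
  m <- read_manifest(path)
  wide <- tidyr::pivot_wider(m, names_from = "modality",
                             values_from = "path", names_prefix = "path_")
  names(wide) <- sub("path_A$", "path_a", names(wide))
  names(wide) <- sub("path_B$", "path_b", names(wide))
  read_one <- function(p) {
    # tolerate manifests moved with their image store: retry relative to
    # the manifest's own directory
    if (!file.exists(p)) {
      alt <- file.path(dirname(path), p)
      if (file.exists(alt)) p <- alt else {
        alt2 <- file.path(dirname(path), "images", basename(p))
        if (file.exists(alt2)) p <- alt2
      }
    }
    png::readPNG(p)
  }
  wide$image_a <- lapply(wide$path_a, read_one)
  wide$image_b <- lapply(wide$path_b, read_one)
  wide
}
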