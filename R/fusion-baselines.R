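# The three classical fusion baselines. They share the extractors, the MA
# block and the training engine with the self-attention strategy, so a
# strategy comparison is a configuration change, not new code.

#' Pool a paired cohort into a single-modality dataset (input-level fusion)
#'
#' Every modality image becomes an independent sample carrying its slice's
#' label and patient id (so patient-level splits stay leakage-free); one
#' shared network is trained on the pooled samples.
#'
#' @param cohort Cohort tibble with `image_a`/`image_b` list-columns.
#' @return Tibble with twice the rows and a single `image` list-column plus
#'   a `modality` column.
#' @export
input_level_dataset <- function(cohort) {
  base <- dplyr::select(cohort, -dplyr::any_of(c("image_a", "image_b",
                                                 "path_a", "path_b")))
  a <- dplyr::mutate(base, modality = "A", image = cohort$image_a)
  b <- dplyr::mutate(base, modality = "B", image = cohort$image_b)
  dplyr::bind_rows(a, b)
}

#' Feature-level fusion of two branch features
#'
#' @param feat_a,feat_b Matrices `[B, d]` (or arrays `[B, h, w, c]`) from
#'   the two branches.
#' @param mode `"concat"` doubles the channel/feature axis; `"add"` is the
#'   elementwise sum (shapes must match).
#' @export
feature_level_fuse <- function(feat_a, feat_b, mode = c("concat", "add")) {
  mode <- match.arg(mode)
  da <- dim(feat_a) %||% length(feat_a)
  db <- dim(feat_b) %||% length(feat_b)
  if (mode == "add") {
    if (!identical(da, db)) stop("add fusion needs identical shapes")
    return(feat_a + feat_b)
  }
  if (is.matrix(feat_a)) {
    if (nrow(feat_a) != nrow(feat_b)) stop("batch size mismatch")
    return(cbind(feat_a, feat_b))
  }
  if (length(da) == 4L) {
    if (!identical(da[1:3], db[1:3])) stop("non-channel dims must match")
    out <- array(0, c(da[1:3], da[4] + db[4]))
    out[, , , seq_len(da[4])] <- feat_a
    out[, , , da[4] + seq_len(db[4])] <- feat_b
    return(out)
  }
  c(feat_a, feat_b)
}

#' Decision-level fusion of per-branch class probabilities
#'
#' Soft mode (default) returns the weighted average of the probability
#' vectors; the recommended weights are proportional to each branch's
#' validation accuracy (renormalised to sum 1). Vote mode takes the
#' majority of the branch argmax decisions, breaking ties by mean
#' probability.
#'
#' @param probs_a Probability matrix `[B, 2]`, or a list of such matrices
#'   (in which case `probs_b` is ignored).
#' @param probs_b Second probability matrix.
#' @param weights Nonnegative weights, one per branch; default equal.
#' @param mode `"soft"` or `"vote"`.
#' @export
decision_level_fuse <- function(probs_a, probs_b = NULL,
                                weights = NULL, mode = c("soft", "vote")) {
  mode <- match.arg(mode)
  plist <- if (is.list(probs_a) && !is.matrix(probs_a)) probs_a
           else list(probs_a, probs_b)
  plist <- plist[!vapply(plist, is.null, logical(1))]
  if (is.null(weights)) weights <- rep(1, length(plist))
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) == 0) stop("weights sum to zero")
  weights <- weights / sum(weights)
  if (mode == "soft") {
    out <- Reduce(`+`, purrr::map2(plist, weights, ~ .x * .y))
    return(out)
  }
  votes <- vapply(plist, function(p) as.integer(p[, 2] > p[, 1]),
                  integer(nrow(plist[[1]])))
  votes <- matrix(votes, ncol = length(plist))
  tally <- votes %*% weights
  soft <- Reduce(`+`, purrr::map2(plist, weights, ~ .x * .y))
  hi <- ifelse(tally > 0.5, 1, ifelse(tally < 0.5, 0, as.integer(soft[, 2] > 0.5)))
  cbind(1 - hi, hi)
}

#' Validation-accuracy-proportional decision weights
#' @param acc_a,acc_b Validation accuracies of the two branches.
#' @export
decision_weights <- function(acc_a, acc_b) {
  w <- c(acc_a, acc_b)
  if (sum(w) == 0) stop("weights sum to zero")
  w / sum(w)
}
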