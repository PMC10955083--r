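# Training and evaluation engine: SGD with cross-entropy + L1, early
# stopping on a monitored validation quantity with best-weight restore,
# k-fold cross-validation and the multi-arm experiment driver.

#' Training configuration
#'
#' Defaults mirror the reference recipe: SGD, learning rate 0.01, 50
#' epochs, batch size 8, cross-entropy loss with L1 regularisation and
#' early stopping.
#'
#' @param learning_rate SGD learning rate.
#' @param epochs Maximum epochs.
#' @param batch_size Slices per batch.
#' @param l1_lambda L1 coefficient on convolution/dense weights (biases and
#'   batchnorm parameters excluded).
#' @param monitor Early-stopping quantity (`"val_loss"` or `"val_accuracy"`).
#' @param patience Epochs without improvement before stopping; best weights
#'   are restored.
#' @param seed Seed controlling batch shuffling.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 50L, batch_size = 8L,
                         l1_lambda = 1e-5, momentum = 0.9,
                         monitor = "val_loss", patience = 10L, seed = 1L,
                         verbose = FALSE) {
  if (l1_lambda < 0) stop("l1_lambda must be nonnegative")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), l1_lambda = l1_lambda,
                 momentum = momentum,
                 monitor = monitor, patience = as.integer(patience),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

rows_for_split <- function(cohort, split) {
  if (!"split" %in% names(cohort)) stop("cohort has no split column; run stratified_patient_split()")
  cohort[!is.na(cohort$split) & cohort$split == split, , drop = FALSE]
}

batch_arrays <- function(rows, input_level = FALSE) {
  if (input_level) {
    imgs <- rows$image
    first <- imgs[[1]]
    out <- array(0, c(length(imgs), dim(first)[1], dim(first)[2], 3L))
    for (i in seq_along(imgs)) out[i, , , ] <- array(imgs[[i]], c(dim(first), 3L))
    list(x1 = out, x2 = NULL, labels = rows$label)
  } else {
    cohort_batch(rows)
  }
}

predict_cohort <- function(model, rows, batch_size = 32L) {
  input_level <- model$mode == "input_level"
  n <- nrow(rows)
  probs <- matrix(0, n, 2L)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    ba <- batch_arrays(rows[idx, , drop = FALSE], input_level)
    fw <- model_forward(model, ba$x1, ba$x2, training = FALSE)
    probs[idx, ] <- fw$probs
  }
  probs
}

eval_loss <- function(model, rows, l1pen, batch_size = 32L) {
  probs <- predict_cohort(model, rows, batch_size)
  eps <- 1e-12
  onehot <- cbind(1 - rows$label, rows$label)
  ce <- -mean(rowSums(onehot * log(probs + eps)))
  list(loss = ce + l1pen, accuracy = mean((probs[, 2] > 0.5) == (rows$label == 1L)))
}

#' Fit a paired-modality classification model
#'
#' Trains an [smmf_model()] on the `train` split of a cohort with SGD
#' (cross-entropy + L1), early-stopping on the `val` split.
#'
#' @param cohort Cohort tibble with filled `split` column and image
#'   list-columns.
#' @param arch,mode,... Passed to [smmf_model()].
#' @param config A [train_config()].
#' @return An object of class `smmf_fit` with elements `model`, `history`
#'   (per-epoch tibble), `config`.
#' @export
fit_smmf <- function(cohort, arch = "compact_test", mode = "saff",
                     config = train_config(), ...) {
  model <- smmf_model(arch = arch, mode = mode, seed = config$seed, ...)
  train_rows <- rows_for_split(cohort, "train")
  val_rows <- rows_for_split(cohort, "val")
  if (nrow(train_rows) == 0L) stop("empty training split")
  if (nrow(val_rows) == 0L) {
    stop("empty validation split (too few patients per class for the ",
         "requested ratios)")
  }
  input_level <- mode == "input_level"
  if (input_level) {
    train_rows <- input_level_dataset(train_rows)
    val_rows_il <- input_level_dataset(val_rows)
  }
  n <- nrow(train_rows)
  bs <- config$batch_size
  best <- list(score = Inf, snap = model_snapshot(model), epoch = 0L)
  wait <- 0L
  opt_state <- NULL
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    set.seed(config$seed * 1000L + epoch)
    ord <- sample.int(n)
    losses <- c()
    for (s in seq(1L, n, by = bs)) {
      idx <- ord[s:min(s + bs - 1L, n)]
      ba <- batch_arrays(train_rows[idx, , drop = FALSE], input_level)
      fw <- model_forward(model, ba$x1, ba$x2, training = TRUE)
      model <- fw$model
      sx <- softmax_xent(fw$logits, ba$labels)
      l1pen <- config$l1_lambda * model_l1(model)
      loss <- sx$loss + l1pen
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", epoch, " (batch starting ", s,
             "); check learning rate / inputs")
      }
      losses <- c(losses, loss)
      grads <- model_backward(model, fw$caches, sx$dlogits)
      upd <- model_update(model, grads, config$learning_rate, config$l1_lambda,
                          config$momentum, opt_state)
      model <- upd$model
      opt_state <- upd$state
    }
    l1pen <- config$l1_lambda * model_l1(model)
    ev <- eval_loss(model, if (input_level) val_rows_il else val_rows, l1pen)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(losses),
      val_loss = ev$loss, val_accuracy = ev$accuracy)
    if (config$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val_acc %.4f",
                      epoch, mean(losses), ev$loss, ev$accuracy))
    }
    score <- if (config$monitor == "val_accuracy") -ev$accuracy else ev$loss
    if (score < best$score - 1e-12) {
      best <- list(score = score, snap = model_snapshot(model), epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model <- model_restore(model, best$snap)
  structure(list(model = model, history = dplyr::bind_rows(history),
                 config = config, mode = mode, arch = arch,
                 best_epoch = best$epoch),
            class = "smmf_fit")
}

#' @export
print.smmf_fit <- function(x, ...) {
  cat("<smmf_fit> mode=", x$mode, " arch=", x$arch, " epochs=",
      nrow(x$history), " best=", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Predicted class probabilities for cohort rows
#'
#' @param object An `smmf_fit` (or `decision_fit`).
#' @param cohort Cohort rows to score.
#' @return The rows with a `prob_high` column appended.
#' @export
predict.smmf_fit <- function(object, cohort, ...) {
  probs <- predict_cohort(object$model, cohort, object$config$batch_size * 4L)
  dplyr::mutate(cohort, prob_high = probs[, 2])
}

#' Evaluate a fitted model on labelled rows
#'
#' @param fit An `smmf_fit` or `decision_fit`.
#' @param cohort Cohort tibble; by default its `test` split is used, or all
#'   rows when `split = NULL` / no split column is present.
#' @param aggregate `"slice"` (default) scores each slice; `"patient"`
#'   averages slice probabilities per patient first.
#' @return One-row metrics tibble (see [metric_report()]).
#' @export
evaluate_fit <- function(fit, cohort, split = "test",
                         aggregate = c("slice", "patient")) {
  aggregate <- match.arg(aggregate)
  rows <- if (!is.null(split) && "split" %in% names(cohort)) {
    rows_for_split(cohort, split)
  } else cohort
  scored <- stats::predict(fit, rows)
  if (aggregate == "patient") {
    scored <- dplyr::summarise(dplyr::group_by(scored, .data$patient_id),
                               label = .data$label[1],
                               prob_high = mean(.data$prob_high), .groups = "drop")
  }
  metric_report(scored$label, scored$prob_high)
}

#' Fit the decision-level fusion baseline
#'
#' Trains one single-modality model per branch and fuses their output
#' distributions with validation-accuracy-proportional weights.
#' @inheritParams fit_smmf
#' @export
fit_decision_level <- function(cohort, arch = "compact_test",
                               config = train_config(), ...) {
  fit_a <- fit_smmf(cohort, arch, mode = "single_a", config = config, ...)
  fit_b <- fit_smmf(cohort, arch, mode = "single_b", config = config, ...)
  val <- rows_for_split(cohort, "val")
  acc_a <- evaluate_fit(fit_a, cohort, split = "val")$accuracy
  acc_b <- evaluate_fit(fit_b, cohort, split = "val")$accuracy
  w <- decision_weights(acc_a, acc_b)
  structure(list(fit_a = fit_a, fit_b = fit_b, weights = w, config = config),
            class = "decision_fit")
}

#' @export
predict.decision_fit <- function(object, cohort, ...) {
  pa <- predict_cohort(object$fit_a$model, cohort)
  pb <- predict_cohort(object$fit_b$model, cohort)
  fused <- decision_level_fuse(pa, pb, weights = object$weights)
  dplyr::mutate(cohort, prob_high = fused[, 2])
}

#' Patient-level k-fold cross-validation
#'
#' Assigns patient-level folds, then for each fold trains a fresh model
#' (fold i = test, next fold = validation, the rest = training) and scores
#' the held-out slices. Fold metrics are aggregated by arithmetic mean and
#' population variance, rounded to 4 decimals.
#'
#' @param cohort Cohort tibble (splits are derived per fold).
#' @param k Number of folds.
#' @param arch,mode,... Model options (see [smmf_model()]).
#' @param config A [train_config()].
#' @return Tibble of per-fold metrics; the aggregation is attached as
#'   attribute `"summary"` and returned by [glance()].
#' @export
cross_validate <- function(cohort, k = 10L, arch = "compact_test",
                           mode = "saff", config = train_config(), ...) {
  folded <- kfold_split(cohort, k, seed = config$seed)
  res <- purrr::map_dfr(seq_len(k), function(i) {
    ck <- fold_split(folded, i, k)
    test_rows <- rows_for_split(ck, "test")
    if (length(unique(test_rows$label)) < 2L) {
      warning("fold ", i, " has a single-class test subset")
    }
    fit <- if (mode == "decision") {
      fit_decision_level(ck, arch, config, ...)
    } else {
      fit_smmf(ck, arch, mode, config, ...)
    }
    dplyr::mutate(evaluate_fit(fit, ck, split = "test"), fold = i,
                  .before = 1)
  })
  attr(res, "summary") <- aggregate_fold_metrics(res)
  class(res) <- c("smmf_cv", class(res))
  res
}

arm_catalog <- function() {
  tibble::tibble(
    arm = c("single_a", "single_b", "saff", "feature_concat", "feature_add",
            "decision", "input_level"),
    mode = c("single_a", "single_b", "saff", "feature_concat", "feature_add",
             "decision", "input_level"))
}

#' Run a multi-arm comparison experiment
#'
#' Trains each requested arm with common seeds and splits and evaluates
#' them on a common test set, so strategy comparisons (single modality vs
#' fusion; MA on/off; transfer learning on/off) are read from one table.
#'
#' @param cohort Training cohort with `split` column.
#' @param arms Character vector of arm names (see `"single_a"`,
#'   `"single_b"`, `"saff"`, `"feature_concat"`, `"feature_add"`,
#'   `"decision"`, `"input_level"`).
#' @param seeds Integer vector; each arm is trained once per seed.
#' @param eval_cohort Optional independent cohort evaluated in full
#'   (defaults to the `test` split of `cohort`).
#' @param use_ma,pretrained Applied to every arm.
#' @param config A [train_config()] (its seed is replaced per run).
#' @return Tibble with one row per arm x seed; per-arm means are attached
#'   as attribute `"summary"`.
#' @export
run_experiment <- function(cohort, arms = c("single_a", "single_b", "saff"),
                           seeds = c(1L, 2L, 3L), eval_cohort = NULL,
                           use_ma = TRUE, pretrained = FALSE,
                           config = train_config(), arch = "compact_test") {
  known <- arm_catalog()$arm
  bad <- setdiff(arms, known)
  if (length(bad)) stop("unknown arm(s): ", paste(bad, collapse = ", "))
  res <- purrr::map_dfr(seeds, function(sd) {
    cfg <- config
    cfg$seed <- as.integer(sd)
    purrr::map_dfr(arms, function(a) {
      fit <- if (a == "decision") {
        fit_decision_level(cohort, arch, cfg, use_ma = use_ma,
                           pretrained = pretrained)
      } else {
        fit_smmf(cohort, arch, mode = a, config = cfg, use_ma = use_ma,
                 pretrained = pretrained)
      }
      m <- if (is.null(eval_cohort)) {
        evaluate_fit(fit, cohort, split = "test")
      } else {
        evaluate_fit(fit, eval_cohort, split = NULL)
      }
      dplyr::mutate(m, arm = a, seed = sd, .before = 1)
    })
  })
  attr(res, "summary") <- dplyr::summarise(
    dplyr::group_by(res, .data$arm),
    dplyr::across(dplyr::all_of(c("accuracy", "f1", "auc")),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  class(res) <- c("smmf_experiment", class(res))
  res
}

#' Fused-representation features for visualisation
#'
#' Returns the representation entering the classifier (the fused vector p
#' for the self-attention head, the pooled token otherwise) for each row.
#' @export
model_features <- function(fit, cohort) {
  model <- fit$model
  input_level <- model$mode == "input_level"
  n <- nrow(cohort)
  feats <- NULL
  for (s in seq(1L, n, by = 32L)) {
    idx <- s:min(s + 31L, n)
    ba <- batch_arrays(cohort[idx, , drop = FALSE], input_level)
    if (model$mode == "saff") {
      fa <- branch_forward(model$branch_a, model$ma_a, ba$x1, FALSE, "A")
      fb <- branch_forward(model$branch_b, model$ma_b, ba$x2, FALSE, "B")
      sf <- saff_forward(model$head, fa$token, fb$token)
      block <- sf$p
    } else {
      ba2 <- if (model$mode == "single_b") ba$x2 else ba$x1
      bf <- branch_forward(model$branch_a, model$ma_a, ba2, FALSE, "A")
      block <- matrix(bf$token, length(idx), model$token_dim)
    }
    feats <- rbind(feats, block)
  }
  feats
}
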