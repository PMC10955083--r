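test_that("metrics match hand arithmetic on a fixed confusion table", {
  # TP=3, FP=1, FN=1, TN=5 -> accuracy 0.8, F1 0.75
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.7, 0.4, 0.6, 0.2, 0.1, 0.3, 0.2, 0.1)
  m <- metric_report(labels, probs)
  expect_equal(m$tp, 3L)
  expect_equal(m$fp, 1L)
  expect_equal(m$fn, 1L)
  expect_equal(m$tn, 5L)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  expect_equal(m$n, 10L)
})

test_that("metric edge cases: perfection, constant scores, single class", {
  perfect <- metric_report(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  const <- metric_report(c(1, 0, 1, 0), rep(0.4, 4))
  expect_equal(const$auc, 0.5)              # midrank ties
  expect_warning(m1 <- metric_report(c(1, 1, 1), c(0.9, 0.8, 0.7)), "single-class")
  expect_true(is.na(m1$auc))
})

test_that("metrics agree with naive definitions over random tables", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    probs <- runif(n)
    m <- metric_report(labels, probs)
    pred <- as.integer(probs > 0.5)
    expect_equal(m$accuracy, round(mean(pred == labels), 4))
    tp <- sum(pred & labels); fp <- sum(pred & !labels); fn <- sum(!pred & labels)
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    expect_equal(m$f1, round(f1, 4))
    # brute-force AUC: pairwise comparisons with half-credit ties
    pos <- probs[labels == 1]; neg <- probs[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(m$auc, round(mean(cmp), 4))
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  labels <- rbinom(80, 1, 0.45)
  scores <- rnorm(80) + labels
  expect_equal(rank_auc(labels, scores),
               as.numeric(suppressMessages(pROC::auc(labels, scores))),
               tolerance = 1e-10)
})

test_that("fold aggregation reproduces the published 10-fold summary", {
  folds <- tibble::tibble(
    accuracy = c(0.9545, 0.9375, 0.9261, 0.9432, 0.9318,
                 0.9261, 0.9375, 0.9375, 0.9602, 0.9204),
    f1 = c(0.9518, 0.9356, 0.9182, 0.9405, 0.9250,
           0.9231, 0.9378, 0.9333, 0.9570, 0.9102),
    auc = c(0.9544, 0.9389, 0.9236, 0.9436, 0.9297,
            0.9269, 0.9409, 0.9370, 0.9591, 0.9170))
  agg <- aggregate_fold_metrics(folds)
  expect_equal(agg$mean[agg$metric == "accuracy"], 0.9375)
  expect_equal(agg$var[agg$metric == "accuracy"], 0.0001)  # population variance
  expect_equal(agg$mean[agg$metric == "f1"], 0.9332)
  expect_equal(agg$var[agg$metric == "f1"], 0.0002)
  expect_equal(agg$mean[agg$metric == "auc"], 0.9371)
  expect_equal(agg$var[agg$metric == "auc"], 0.0002)
  # sample variance would NOT reproduce the printed value
  expect_false(round(var(folds$accuracy), 4) == 0.0001)
  same <- aggregate_fold_metrics(tibble::tibble(accuracy = rep(0.9, 5)))
  expect_equal(same$var, 0)
})

test_that("training is deterministic and the L1 penalty is nonnegative", {
  cohort <- stratified_patient_split(small_cohort(seed = 6L, n = c(6L, 6L),
                                                  slices = c(2L, 2L)),
                                     seed = 6L)
  cfg <- train_config(epochs = 2L, patience = 2L, seed = 6L)
  f1 <- fit_smmf(cohort, mode = "single_a", config = cfg, use_ma = FALSE)
  f2 <- fit_smmf(cohort, mode = "single_a", config = cfg, use_ma = FALSE)
  expect_identical(f1$history, f2$history)
  expect_identical(mpfusion:::model_snapshot(f1$model),
                   mpfusion:::model_snapshot(f2$model))
  # objective with l1 > 0 exceeds plain cross-entropy on identical weights
  l1 <- mpfusion:::model_l1(f1$model)
  expect_gt(l1, 0)
  rows <- cohort[cohort$split == "val", ]
  with_pen <- mpfusion:::eval_loss(f1$model, rows, 1e-4 * l1)
  without <- mpfusion:::eval_loss(f1$model, rows, 0)
  expect_gt(with_pen$loss, without$loss)
})

test_that("training reduces the loss on a learnable synthetic cohort", {
  cohort <- stratified_patient_split(
    generate_cohort(synth_config(c(6L, 6L), slices_per_patient_range = c(2L, 3L),
                                 image_size = 32L, seed = 8L)),
    seed = 8L)
  cfg <- train_config(epochs = 6L, patience = 6L, seed = 8L)
  fit <- fit_smmf(cohort, mode = "single_b", config = cfg, use_ma = FALSE)
  h <- fit$history
  expect_lt(h$train_loss[6], h$train_loss[1])
  expect_equal(nrow(h), 6L)
  expect_error(fit_smmf(cohort[cohort$split == "test", ], config = cfg),
               "empty training split")
})

test_that("early stopping restores the best-monitored weights", {
  cohort <- stratified_patient_split(small_cohort(seed = 9L, n = c(6L, 6L),
                                                  slices = c(2L, 2L)),
                                     seed = 9L)
  cfg <- train_config(epochs = 10L, patience = 2L, seed = 9L,
                      learning_rate = 0.05)
  fit <- fit_smmf(cohort, mode = "single_a", config = cfg, use_ma = FALSE)
  h <- fit$history
  expect_lte(nrow(h), 10L)
  expect_equal(fit$best_epoch, which.min(h$val_loss))
})

test_that("cross-validation tests every patient exactly once and aggregates", {
  cohort <- small_cohort(seed = 10L, n = c(5L, 5L), slices = c(1L, 2L))
  cfg <- train_config(epochs = 1L, patience = 1L, seed = 10L)
  res <- suppressWarnings(
    cross_validate(cohort, k = 3L, mode = "single_b", config = cfg,
                   use_ma = FALSE))
  expect_equal(nrow(res), 3L)
  expect_s3_class(res, "smmf_cv")
  s <- attr(res, "summary")
  expect_setequal(s$metric, c("accuracy", "f1", "auc"))
  expect_equal(s$mean[s$metric == "accuracy"],
               round(mean(res$accuracy), 4))
  g <- glance(res)
  expect_true(all(c("accuracy_mean", "accuracy_var") %in% names(g)))
})

test_that("the experiment driver runs arms on common seeds and is reproducible", {
  cohort <- stratified_patient_split(small_cohort(seed = 11L, n = c(6L, 6L),
                                                  slices = c(2L, 2L)),
                                     seed = 11L)
  cfg <- train_config(epochs = 2L, patience = 2L)
  expect_error(run_experiment(cohort, arms = "kitchen_sink", config = cfg),
               "unknown arm")
  r1 <- run_experiment(cohort, arms = c("single_a", "saff"), seeds = 4L,
                       config = cfg, use_ma = FALSE)
  r2 <- run_experiment(cohort, arms = c("single_a", "saff"), seeds = 4L,
                       config = cfg, use_ma = FALSE)
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
  expect_setequal(r1$arm, c("single_a", "saff"))
  expect_true(all(c("accuracy", "f1", "auc") %in% names(r1)))
  # MA on and off both run (plumbing contract)
  r3 <- run_experiment(cohort, arms = "single_a", seeds = 4L, config = cfg,
                       use_ma = TRUE)
  expect_equal(nrow(r3), 1L)
  expect_s3_class(glance(r1), "tbl_df")
})

test_that("decision-level fit fuses the two branch fits with valid weights", {
  cohort <- stratified_patient_split(small_cohort(seed = 12L, n = c(6L, 6L),
                                                  slices = c(2L, 2L)),
                                     seed = 12L)
  cfg <- train_config(epochs = 2L, patience = 2L, seed = 12L)
  fit <- fit_decision_level(cohort, config = cfg, use_ma = FALSE)
  expect_s3_class(fit, "decision_fit")
  expect_equal(sum(fit$weights), 1)
  scored <- predict(fit, cohort[1:4, ])
  expect_true(all(scored$prob_high >= 0 & scored$prob_high <= 1))
})

test_that("t-SNE embeds deterministically and keeps duplicates together", {
  set.seed(13)
  X <- rbind(matrix(rnorm(40 * 3), 40),
             matrix(rnorm(40 * 3, mean = 4), 40))
  lab <- rep(0:1, each = 40)
  e1 <- tsne_embed(X, lab, perplexity = 8, max_iter = 120, seed = 2)
  e2 <- tsne_embed(X, lab, perplexity = 8, max_iter = 120, seed = 2)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 80L)
  expect_error(tsne_embed(X[1:10, ], perplexity = 8), "too few")
  # duplicated input points stay close relative to the embedding spread
  Xd <- rbind(X, X[1, , drop = FALSE])
  ed <- tsne_embed(Xd, max_iter = 120, seed = 2)
  dup <- sqrt(sum((ed[81, 1:2] - ed[1, 1:2])^2))
  spread <- mean(sqrt(rowSums((as.matrix(ed[, 1:2]) -
                                 colMeans(as.matrix(ed[, 1:2])))^2)))
  expect_lt(dup, spread / 2)
  d <- withr::local_tempdir()
  out <- tsne_export(X, lab, file.path(d, "emb.csv"), perplexity = 8,
                     max_iter = 50, seed = 1)
  expect_true(file.exists(file.path(d, "emb.csv")))
  expect_equal(nrow(utils::read.csv(file.path(d, "emb.csv"))), 80L)
})

test_that("tidiers expose history, folds and summaries as tibbles", {
  cohort <- stratified_patient_split(small_cohort(seed = 14L, n = c(6L, 6L),
                                                  slices = c(2L, 2L)),
                                     seed = 14L)
  cfg <- train_config(epochs = 2L, patience = 2L, seed = 14L)
  fit <- fit_smmf(cohort, mode = "single_a", config = cfg, use_ma = FALSE)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  emb <- tibble::tibble(x = rnorm(10), y = rnorm(10), label = rep(0:1, 5))
  expect_s3_class(plot_embedding(emb), "ggplot")
})
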