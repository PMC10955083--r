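# Exact t-SNE (quadratic in n) for visual validation of the learned
# representations. Utility only: no quantitative claims rest on it.

#' t-SNE embedding of a feature matrix
#'
#' Standard t-distributed stochastic neighbour embedding with per-point
#' bandwidths matched to `perplexity` by bisection, early exaggeration and
#' momentum gradient descent. Deterministic under a fixed seed.
#'
#' @param features Numeric matrix `[n, p]`.
#' @param labels Optional length-n labels carried into the output.
#' @param perplexity Effective neighbour count; requires
#'   `n >= 3 * perplexity + 2`.
#' @param max_iter Gradient-descent iterations.
#' @param seed Seed for the initial layout.
#' @return Tibble with columns `x`, `y` and (if given) `label`.
#' @export
tsne_embed <- function(features, labels = NULL, perplexity = 10,
                       max_iter = 300L, seed = 1L) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 3 * perplexity + 2) {
    stop("too few samples (", n, ") for perplexity ", perplexity)
  }
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 50) 4 else 1
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (iter < 100) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    G <- mom * G - 100 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  out <- tibble::tibble(x = Y[, 1], y = Y[, 2])
  if (!is.null(labels)) out$label <- labels
  out
}

#' Export a 2-D embedding for plotting
#'
#' @param features,labels,... Passed to [tsne_embed()].
#' @param path CSV destination.
#' @return The embedding tibble, invisibly.
#' @export
tsne_export <- function(features, labels, path, ...) {
  emb <- tsne_embed(features, labels, ...)
  utils::write.csv(emb, path, row.names = FALSE)
  invisible(emb)
}
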