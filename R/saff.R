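# Self-attention feature fusion (SAFF): each modality's feature map is
# pooled to a d-dimensional token, spliced with a learnable class token into
# a [B, 3, d] bundle, and passed through single-head scaled dot-product
# attention. The attention matrix g carries modality-specificity, the
# attended values f the commonality; h = theta * V + f re-injects the
# original features, and the fused vector p splices g and h for a two-layer
# classifier.

#' Pool a feature map to a modality token
#'
#' Global average pooling over the spatial axes followed by token-axis
#' expansion: `[B, h, w, d]` becomes `[B, 1, d]`.
#' @param fmap Feature map array `[B, h, w, d]`.
#' @export
pool_and_tokenize <- function(fmap) {
  d <- dim(fmap)
  if (length(d) != 4L) stop("expected a [B, h, w, d] feature map")
  if (d[2] < 1L || d[3] < 1L) stop("zero spatial extent")
  tok <- gap_forward(fmap)$out
  dim(tok) <- c(d[1], 1L, d[4])
  tok
}

#' Splice modality tokens with the class token
#'
#' Token order is fixed as (modality A, modality B, cls); the class token is
#' shared across the batch.
#' @param token_a,token_b Tokens `[B, 1, d]`.
#' @param cls_token Numeric vector of length `d`.
#' @return Token bundle `[B, 3, d]`.
#' @export
assemble_tokens <- function(token_a, token_b, cls_token) {
  da <- dim(token_a); db <- dim(token_b)
  if (!identical(da, db) || da[3] != length(cls_token)) {
    stop("token dimension mismatch")
  }
  B <- da[1]; d <- da[3]
  out <- array(0, c(B, 3L, d))
  out[, 1L, ] <- token_a[, 1L, ]
  out[, 2L, ] <- token_b[, 1L, ]
  out[, 3L, ] <- matrix(cls_token, B, d, byrow = TRUE)
  out
}

#' Scaled dot-product attention matrix
#'
#' `g = softmax(Q K' / sqrt(d))`, softmax taken along the key axis so every
#' row of `g` sums to one.
#' @param Q,K Projected token arrays `[B, 3, d]`.
#' @param d Key dimension used in the scaling.
#' @return Attention array `[B, 3, 3]`.
#' @export
attention_matrix <- function(Q, K, d = dim(Q)[3]) {
  B <- dim(Q)[1]
  g <- array(0, c(B, 3L, 3L))
  for (b in seq_len(B)) {
    S <- matrix(Q[b, , ], 3L) %*% t(matrix(K[b, , ], 3L)) / sqrt(d)
    if (any(!is.finite(S))) stop("non-finite attention logits")
    g[b, , ] <- softmax_rows(S)
  }
  g
}

#' Common features and their residual enrichment
#'
#' `f = g V` (attention-weighted values) and `h = theta * V + f`, with
#' `theta` the scalar coefficient preserving the original features.
#' @param g Attention array `[B, 3, 3]`.
#' @param V Value array `[B, 3, d]`.
#' @param theta Nonnegative scalar.
#' @return `list(f, h)`, both `[B, 3, d]`.
#' @export
common_features <- function(g, V, theta = 1) {
  if (theta < 0) stop("theta must be nonnegative")
  B <- dim(V)[1]; d <- dim(V)[3]
  f <- array(0, c(B, 3L, d))
  for (b in seq_len(B)) {
    f[b, , ] <- matrix(g[b, , ], 3L) %*% matrix(V[b, , ], 3L)
  }
  list(f = f, h = theta * V + f)
}

#' Splice specific and common features into the fused vector
#'
#' `readout = "full"` (default) concatenates the column-major flattened
#' attention matrix `g` (9 values) with the flattened `h` (3 d values),
#' giving length `3 d + 9`; `readout = "cls"` concatenates the class-token
#' row of `h` with the class-token row of `g`, giving length `d + 3`.
#' @param g Attention array `[B, 3, 3]`.
#' @param h Residual-enriched features `[B, 3, d]`.
#' @export
fuse_features <- function(g, h, readout = c("full", "cls")) {
  readout <- match.arg(readout)
  B <- dim(h)[1]; d <- dim(h)[3]
  if (readout == "full") {
    p <- matrix(0, B, 3L * d + 9L)
    for (b in seq_len(B)) {
      p[b, ] <- c(as.vector(matrix(g[b, , ], 3L)), as.vector(matrix(h[b, , ], 3L)))
    }
  } else {
    p <- matrix(0, B, d + 3L)
    for (b in seq_len(B)) p[b, ] <- c(h[b, 3L, ], g[b, 3L, ])
  }
  p
}

#' Construct a SAFF fusion head
#'
#' @param d Token dimension (equals the MA output channels; 512 default).
#' @param theta Residual coefficient (default 1).
#' @param theta_learnable Update `theta` by gradient descent.
#' @param readout `"full"` or `"cls"` (see [fuse_features()]).
#' @param hidden Width of the first fully connected classifier layer.
#' @param seed Seed for initialisation; the class token is drawn from a
#'   zero-mean Gaussian with sd 0.02.
#' @return An object of class `saff_head`.
#' @export
saff_head <- function(d = 512L, theta = 1, theta_learnable = FALSE,
                      readout = c("full", "cls"), hidden = 256L, seed = 1L) {
  readout <- match.arg(readout)
  if (theta < 0) stop("theta must be nonnegative")
  set.seed(seed)
  d <- as.integer(d)
  pdim <- if (readout == "full") 3L * d + 9L else d + 3L
  par <- list(
    q = list(weight = init_dense(d, d, sd = sqrt(1 / d))),
    k = list(weight = init_dense(d, d, sd = sqrt(1 / d))),
    v = list(weight = init_dense(d, d, sd = sqrt(1 / d))),
    cls = stats::rnorm(d, sd = 0.02),
    theta = theta,
    fc1 = list(weight = init_dense(pdim, hidden), bias = numeric(hidden)),
    fc2 = list(weight = init_dense(hidden, 2L, sd = sqrt(1 / hidden)), bias = numeric(2L))
  )
  structure(list(d = d, readout = readout, hidden = as.integer(hidden),
                 theta_learnable = isTRUE(theta_learnable), par = par),
            class = "saff_head")
}

#' Classify a fused representation
#'
#' Two fully connected layers (ReLU in between) followed by a softmax over
#' the two tumour grades; column 2 is the high-grade probability.
#' @param head A [saff_head()].
#' @param p Fused representation matrix `[B, pdim]`.
#' @export
classify_fused <- function(head, p) {
  z1 <- dense_forward(p, head$par$fc1$weight, head$par$fc1$bias)
  a1 <- relu_forward(z1$out)
  z2 <- dense_forward(a1$out, head$par$fc2$weight, head$par$fc2$bias)
  softmax_rows(z2$out)
}

#' Run the SAFF head forward
#'
#' @param head A [saff_head()].
#' @param token_a,token_b Modality tokens `[B, 1, d]`.
#' @return `list(probs, logits, g, f, h, p, cache)`.
#' @export
saff_forward <- function(head, token_a, token_b, keep_cache = FALSE) {
  d <- head$d
  Tk <- assemble_tokens(token_a, token_b, head$par$cls)
  B <- dim(Tk)[1]
  Wq <- head$par$q$weight; Wk <- head$par$k$weight; Wv <- head$par$v$weight
  Tm <- matrix(Tk, nrow = B * 3L)           # (B*3) x d, batch fastest
  Q <- Tm %*% Wq; K <- Tm %*% Wk; V <- Tm %*% Wv
  dim(Q) <- c(B, 3L, d); dim(K) <- c(B, 3L, d); dim(V) <- c(B, 3L, d)
  g <- attention_matrix(Q, K, d)
  cf <- common_features(g, V, head$par$theta)
  p <- fuse_features(g, cf$h, head$readout)
  z1 <- dense_forward(p, head$par$fc1$weight, head$par$fc1$bias)
  a1 <- relu_forward(z1$out)
  z2 <- dense_forward(a1$out, head$par$fc2$weight, head$par$fc2$bias)
  probs <- softmax_rows(z2$out)
  cache <- if (keep_cache) {
    list(Tk = Tk, Q = Q, K = K, V = V, g = g, f = cf$f, h = cf$h, p = p,
         z1 = z1$cache, a1 = a1$cache, z2 = z2$cache, B = B)
  } else NULL
  list(probs = probs, logits = z2$out, g = g, f = cf$f, h = cf$h, p = p,
       cache = cache)
}

# Backward pass from a gradient on the classifier logits down to the input
# tokens; returns gradients for every head parameter plus dtoken_a/dtoken_b.
#' @noRd
saff_backward <- function(head, cache, dlogits) {
  d <- head$d
  B <- cache$B
  b2 <- dense_backward(dlogits, head$par$fc2$weight, cache$z2)
  ba <- relu_backward(b2$dx, cache$a1)
  b1 <- dense_backward(ba$dx, head$par$fc1$weight, cache$z1)
  dp <- b1$dx
  dg <- array(0, c(B, 3L, 3L))
  dh <- array(0, c(B, 3L, d))
  if (head$readout == "full") {
    for (b in seq_len(B)) {
      dg[b, , ] <- matrix(dp[b, 1:9], 3L)
      dh[b, , ] <- matrix(dp[b, 9L + seq_len(3L * d)], 3L)
    }
  } else {
    for (b in seq_len(B)) {
      dh[b, 3L, ] <- dp[b, seq_len(d)]
      dg[b, 3L, ] <- dp[b, d + 1:3]
    }
  }
  theta <- head$par$theta
  dT <- array(0, c(B, 3L, d))
  dWq <- matrix(0, d, d); dWk <- matrix(0, d, d); dWv <- matrix(0, d, d)
  dtheta <- 0
  sqd <- sqrt(d)
  for (b in seq_len(B)) {
    Tb <- matrix(cache$Tk[b, , ], 3L)
    Qb <- matrix(cache$Q[b, , ], 3L)
    Kb <- matrix(cache$K[b, , ], 3L)
    Vb <- matrix(cache$V[b, , ], 3L)
    gb <- matrix(cache$g[b, , ], 3L)
    dhb <- matrix(dh[b, , ], 3L)
    dgb <- matrix(dg[b, , ], 3L)
    dfb <- dhb                               # h = theta*V + f
    dVb <- theta * dhb
    dtheta <- dtheta + sum(Vb * dhb)
    dgb <- dgb + dfb %*% t(Vb)               # f = g V
    dVb <- dVb + crossprod(gb, dfb)
    dS <- gb * (dgb - rowSums(dgb * gb))     # softmax rows
    dQb <- dS %*% Kb / sqd
    dKb <- crossprod(dS, Qb) / sqd
    dT[b, , ] <- dQb %*% t(head$par$q$weight) +
      dKb %*% t(head$par$k$weight) +
      dVb %*% t(head$par$v$weight)
    dWq <- dWq + crossprod(Tb, dQb)
    dWk <- dWk + crossprod(Tb, dKb)
    dWv <- dWv + crossprod(Tb, dVb)
  }
  dta <- array(dT[, 1L, , drop = FALSE], c(B, 1L, d))
  dtb <- array(dT[, 2L, , drop = FALSE], c(B, 1L, d))
  dcls <- colSums(matrix(dT[, 3L, ], B))
  grads <- list(q = list(weight = dWq), k = list(weight = dWk),
                v = list(weight = dWv), cls = dcls,
                fc1 = list(weight = b1$dW, bias = b1$db),
                fc2 = list(weight = b2$dW, bias = b2$db))
  if (head$theta_learnable) grads$theta <- dtheta
  list(dtoken_a = dta, dtoken_b = dtb, grads = grads, dtheta = dtheta)
}
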