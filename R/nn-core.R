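# Minimal neural-network core: 4-axis feature maps stored as R arrays with
# dims (batch, height, width, channels); convolution is im2col + BLAS matmul.
# Every primitive has a forward returning list(out, cache) and a backward
# returning list(dx, grads); gradients are checked against finite differences
# in the test suite.

.idx_cache <- new.env(parent = emptyenv())

# Linear-index plans for im2col. `base` enumerates (batch, out_row, out_col)
# positions, `off` enumerates (k_row, k_col, channel) kernel taps; the im2col
# matrix is X_padded[outer(base, off, "+")].
conv_index_plan <- function(B, H, W, C, kh, kw, stride, ph, pw) {
  key <- paste(B, H, W, C, kh, kw, stride, ph, pw, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * ph
  Wp <- W + 2L * pw
  OH <- (Hp - kh) %/% stride + 1L
  OW <- (Wp - kw) %/% stride + 1L
  b  <- seq_len(B)
  oi <- (seq_len(OH) - 1L) * stride
  oj <- (seq_len(OW) - 1L) * stride
  base <- rep(b, times = OH * OW) +
    B * rep(rep(oi, each = B), times = OW) +
    B * Hp * rep(oj, each = B * OH)
  ki <- seq_len(kh) - 1L
  kj <- seq_len(kw) - 1L
  cc <- seq_len(C) - 1L
  off <- B * rep(ki, times = kw * C) +
    B * Hp * rep(rep(kj, each = kh), times = C) +
    B * Hp * Wp * rep(cc, each = kh * kw)
  plan <- list(base = base, off = off, Hp = Hp, Wp = Wp, OH = OH, OW = OW)
  .idx_cache[[key]] <- plan
  plan
}

pad_nhwc <- function(x, ph, pw, value = 0) {
  d <- dim(x)
  if (ph == 0L && pw == 0L) return(x)
  out <- array(value, c(d[1], d[2] + 2L * ph, d[3] + 2L * pw, d[4]))
  out[, ph + seq_len(d[2]), pw + seq_len(d[3]), ] <- x
  out
}

same_pad <- function(k) as.integer((k - 1L) %/% 2L)

# ---- convolution -----------------------------------------------------------

#' @noRd
conv2d_forward <- function(x, W, b, stride = 1L, padding = c("same", "valid"),
                           keep_cache = TRUE) {
  padding <- match.arg(padding)
  d <- dim(x)
  kd <- dim(W)   # (kh, kw, Cin, Cout)
  stopifnot(d[4] == kd[3])
  ph <- if (padding == "same") same_pad(kd[1]) else 0L
  pw <- if (padding == "same") same_pad(kd[2]) else 0L
  plan <- conv_index_plan(d[1], d[2], d[3], d[4], kd[1], kd[2], as.integer(stride), ph, pw)
  xp <- pad_nhwc(x, ph, pw)
  xcol <- matrix(xp[as.vector(outer(plan$base, plan$off, "+"))],
                 nrow = length(plan$base))
  wmat <- matrix(W, nrow = kd[1] * kd[2] * kd[3])
  y <- xcol %*% wmat
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(d[1], plan$OH, plan$OW, kd[4])
  cache <- if (keep_cache) {
    list(xcol = xcol, plan = plan, dims = d, kdims = kd,
         stride = as.integer(stride), ph = ph, pw = pw)
  } else NULL
  list(out = y, cache = cache)
}

#' @noRd
conv2d_backward <- function(dy, W, cache) {
  kd <- cache$kdims
  d <- cache$dims
  plan <- cache$plan
  dym <- matrix(dy, ncol = kd[4])
  dW <- crossprod(cache$xcol, dym)
  dim(dW) <- kd
  db <- colSums(dym)
  wmat <- matrix(W, nrow = kd[1] * kd[2] * kd[3])
  dxcol <- tcrossprod(dym, wmat)
  dxp <- numeric(d[1] * plan$Hp * plan$Wp * d[4])
  base <- plan$base
  off <- plan$off
  for (q in seq_along(off)) {
    idx <- base + off[q]
    dxp[idx] <- dxp[idx] + dxcol[, q]
  }
  dim(dxp) <- c(d[1], plan$Hp, plan$Wp, d[4])
  dx <- if (cache$ph > 0L || cache$pw > 0L) {
    dxp[, cache$ph + seq_len(d[2]), cache$pw + seq_len(d[3]), , drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

# ---- pooling ---------------------------------------------------------------

pool_index_plan <- function(B, H, W, C, k, stride, ph, pw) {
  key <- paste("pool", B, H, W, C, k, stride, ph, pw, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * ph
  Wp <- W + 2L * pw
  OH <- (Hp - k) %/% stride + 1L
  OW <- (Wp - k) %/% stride + 1L
  b  <- seq_len(B)
  oi <- (seq_len(OH) - 1L) * stride
  oj <- (seq_len(OW) - 1L) * stride
  cc <- seq_len(C) - 1L
  base <- rep(b, times = OH * OW * C) +
    B * rep(rep(oi, each = B), times = OW * C) +
    B * Hp * rep(rep(oj, each = B * OH), times = C) +
    B * Hp * Wp * rep(cc, each = B * OH * OW)
  ki <- seq_len(k) - 1L
  kj <- seq_len(k) - 1L
  off <- B * rep(ki, times = k) + B * Hp * rep(kj, each = k)
  plan <- list(base = base, off = off, Hp = Hp, Wp = Wp, OH = OH, OW = OW)
  .idx_cache[[key]] <- plan
  plan
}

#' @noRd
maxpool_forward <- function(x, k, stride = k, padding = 0L, keep_cache = TRUE) {
  d <- dim(x)
  plan <- pool_index_plan(d[1], d[2], d[3], d[4], as.integer(k), as.integer(stride),
                          as.integer(padding), as.integer(padding))
  xp <- pad_nhwc(x, as.integer(padding), as.integer(padding), value = -Inf)
  m <- matrix(xp[as.vector(outer(plan$base, plan$off, "+"))],
              nrow = length(plan$base))
  amax <- max.col(m, ties.method = "first")
  y <- m[cbind(seq_along(amax), amax)]
  dim(y) <- c(d[1], plan$OH, plan$OW, d[4])
  cache <- if (keep_cache) {
    list(plan = plan, amax = amax, dims = d, padding = as.integer(padding))
  } else NULL
  list(out = y, cache = cache)
}

#' @noRd
maxpool_backward <- function(dy, cache) {
  d <- cache$dims
  plan <- cache$plan
  tgt <- plan$base + plan$off[cache$amax]
  agg <- rowsum(as.numeric(dy), group = tgt)
  dxp <- numeric(d[1] * plan$Hp * plan$Wp * d[4])
  dxp[as.numeric(rownames(agg))] <- agg
  dim(dxp) <- c(d[1], plan$Hp, plan$Wp, d[4])
  p <- cache$padding
  dx <- if (p > 0L) dxp[, p + seq_len(d[2]), p + seq_len(d[3]), , drop = FALSE] else dxp
  list(dx = dx)
}

#' @noRd
avgpool_forward <- function(x, k, stride = k, keep_cache = TRUE) {
  d <- dim(x)
  plan <- pool_index_plan(d[1], d[2], d[3], d[4], as.integer(k), as.integer(stride), 0L, 0L)
  m <- matrix(x[as.vector(outer(plan$base, plan$off, "+"))],
              nrow = length(plan$base))
  y <- rowMeans(m)
  dim(y) <- c(d[1], plan$OH, plan$OW, d[4])
  cache <- if (keep_cache) list(plan = plan, dims = d, k = as.integer(k)) else NULL
  list(out = y, cache = cache)
}

#' @noRd
avgpool_backward <- function(dy, cache) {
  d <- cache$dims
  plan <- cache$plan
  share <- as.numeric(dy) / (cache$k^2)
  dx <- numeric(prod(d))
  for (q in seq_along(plan$off)) {
    idx <- plan$base + plan$off[q]
    dx[idx] <- dx[idx] + share
  }
  dim(dx) <- d
  list(dx = dx)
}

# Global average pool over the spatial axes: (B,H,W,C) -> (B,C).
#' @noRd
gap_forward <- function(x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])           # columns ordered (h, w, c)
  y <- matrix(0, d[1], d[4])
  hw <- d[2] * d[3]
  for (c in seq_len(d[4])) {
    cols <- ((c - 1L) * hw + 1L):(c * hw)
    y[, c] <- rowSums(xm[, cols, drop = FALSE]) / hw
  }
  list(out = y, cache = list(dims = d))
}

#' @noRd
gap_backward <- function(dy, cache) {
  d <- cache$dims
  hw <- d[2] * d[3]
  dx <- array(0, d)
  for (c in seq_len(d[4])) dx[, , , c] <- dy[, c] / hw
  list(dx = dx)
}

# Global max pool over the spatial axes: (B,H,W,C) -> (B,C).
#' @noRd
gmp_forward <- function(x) {
  d <- dim(x)
  hw <- d[2] * d[3]
  xm <- matrix(aperm(x, c(2, 3, 1, 4)), nrow = hw)  # hw x (B*C)
  amax <- max.col(t(xm), ties.method = "first")
  y <- matrix(xm[cbind(amax, seq_len(d[1] * d[4]))], d[1], d[4])
  list(out = y, cache = list(dims = d, amax = amax))
}

#' @noRd
gmp_backward <- function(dy, cache) {
  d <- cache$dims
  hw <- d[2] * d[3]
  dxm <- matrix(0, hw, d[1] * d[4])
  dxm[cbind(cache$amax, seq_len(d[1] * d[4]))] <- as.numeric(dy)
  dim(dxm) <- c(d[2], d[3], d[1], d[4])
  list(dx = aperm(dxm, c(3, 1, 2, 4)))
}

# ---- batch normalisation ---------------------------------------------------

# Per-channel over (batch, height, width); population statistics in training,
# running statistics (momentum 0.1) at evaluation.
#' @noRd
batchnorm_forward <- function(x, gamma, beta, run_mean, run_var,
                              training = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[4]
  xm <- matrix(x, ncol = C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- sweep(xm, 2, mu)
    new_mean <- run_mean
    new_var <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(y) <- d
  list(out = y,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, dims = d,
                    training = training),
       run_mean = new_mean, run_var = new_var)
}

#' @noRd
batchnorm_backward <- function(dy, cache) {
  d <- cache$dims
  C <- d[4]
  N <- prod(d) / C
  dym <- matrix(dy, ncol = C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  if (cache$training) {
    dxhat <- sweep(dym, 2, cache$gamma, "*")
    dx <- sweep(
      dxhat - matrix(colMeans(dxhat), nrow(dxhat), C, byrow = TRUE) -
        cache$xhat * matrix(colMeans(dxhat * cache$xhat), nrow(dxhat), C, byrow = TRUE),
      2, cache$inv_sd, "*")
  } else {
    dx <- sweep(sweep(dym, 2, cache$gamma, "*"), 2, cache$inv_sd, "*")
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- dense / activations / loss -------------------------------------------

#' @noRd
dense_forward <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2, b, "+")
  list(out = y, cache = list(x = x))
}

#' @noRd
dense_backward <- function(dy, W, cache) {
  list(dx = tcrossprod(dy, W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

#' @noRd
relu_forward <- function(x) list(out = pmax(x, 0), cache = list(mask = x > 0))

#' @noRd
relu_backward <- function(dy, cache) list(dx = dy * cache$mask)

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy of softmax probabilities against 0/1 labels (columns =
# classes, column 2 = positive class). Returns loss and gradient w.r.t. the
# pre-softmax logits.
#' @noRd
softmax_xent <- function(logits, labels) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  onehot <- cbind(1 - labels, labels)
  eps <- 1e-12
  loss <- -mean(rowSums(onehot * log(p + eps)))
  dlogits <- (p - onehot) / n
  list(loss = loss, probs = p, dlogits = dlogits)
}

# ---- parameter-tree utilities ---------------------------------------------

# Parameters live in nested lists whose leaves are numeric arrays; gradients
# mirror the structure. Leaves named "kernel" or "weight" count as weights for
# the L1 penalty; biases and batchnorm scale/shift are excluded.

.weight_leaves <- c("kernel", "weight")

#' @noRd
tree_count <- function(x) {
  if (is.numeric(x)) return(length(x))
  if (is.list(x)) return(sum(vapply(x, tree_count, numeric(1))))
  0
}

# SGD with optional classical momentum; `vel` mirrors `par` (created lazily)
# and is returned alongside the updated parameters.
#' @noRd
tree_sgd <- function(par, grad, lr, l1 = 0, momentum = 0, vel = NULL) {
  if (is.null(vel)) vel <- list()
  for (nm in names(par)) {
    p <- par[[nm]]
    g <- grad[[nm]]
    if (is.null(g)) next
    if (is.numeric(p)) {
      if (l1 > 0 && nm %in% .weight_leaves) g <- g + l1 * sign(p)
      if (momentum > 0) {
        v <- vel[[nm]]
        if (is.null(v)) v <- 0 * p
        v <- momentum * v - lr * g
        vel[[nm]] <- v
        par[[nm]] <- p + v
      } else {
        par[[nm]] <- p - lr * g
      }
    } else if (is.list(p)) {
      r <- tree_sgd(p, g, lr, l1, momentum, vel[[nm]])
      par[[nm]] <- r$par
      vel[[nm]] <- r$vel
    }
  }
  list(par = par, vel = vel)
}

#' @noRd
tree_apply_sgd <- function(par, grad, lr, l1 = 0) {
  tree_sgd(par, grad, lr, l1)$par
}

#' @noRd
tree_l1 <- function(par) {
  if (is.numeric(par)) return(0)
  s <- 0
  for (nm in names(par)) {
    p <- par[[nm]]
    if (is.numeric(p)) {
      if (nm %in% .weight_leaves) s <- s + sum(abs(p))
    } else if (is.list(p)) s <- s + tree_l1(p)
  }
  s
}

# He-normal initialisation for convolution and dense weights.
#' @noRd
init_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' @noRd
init_dense <- function(din, dout, sd = sqrt(2 / din)) {
  matrix(stats::rnorm(din * dout, sd = sd), din, dout)
}
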