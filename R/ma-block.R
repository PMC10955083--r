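# Multiscale attention (MA) block: 1x1 channel reduction, two parallel IC
# paths (inception-style multiscale convolutions followed by CBAM channel +
# spatial attention), re-projection, and an additive skip connection from the
# reduced features. Channel counts are configuration, not constants, so the
# block attaches to any backbone.

#' MA block configuration
#'
#' @param in_channels Channels of the incoming feature map (1024 for the
#'   default backbone).
#' @param reduced_channels Channels after the pointwise reduction; defaults
#'   to `in_channels / 2`.
#' @param cbam_ratio Channel-attention bottleneck ratio (hidden width =
#'   `reduced_channels / cbam_ratio`, at least 1).
#' @param spatial_kernel Kernel size of the spatial-attention convolution.
#' @param combine How the two IC paths are merged before re-projection:
#'   `"concat"` (channel concatenation, then 1x1 conv back to
#'   `reduced_channels`) or `"add"`.
#' @param batchnorm Batch-normalise after every convolution. The default
#'   suits full-size backbones; disable for the norm-free compact
#'   configuration used on very small cohorts, where batchnorm's train/eval
#'   statistics mismatch can dominate weak signals.
#' @return A list of class `ma_config`.
#' @export
ma_config <- function(in_channels = 1024L, reduced_channels = in_channels %/% 2L,
                      cbam_ratio = 16L, spatial_kernel = 7L,
                      combine = c("concat", "add"), batchnorm = TRUE) {
  combine <- match.arg(combine)
  in_channels <- as.integer(in_channels)
  reduced_channels <- as.integer(reduced_channels)
  if (in_channels <= 0L || reduced_channels <= 0L) stop("channel counts must be positive")
  if (reduced_channels %% 4L != 0L) {
    stop("reduced_channels must be divisible by 4 (one quarter per inception branch)")
  }
  structure(list(in_channels = in_channels, reduced_channels = reduced_channels,
                 cbam_ratio = as.integer(cbam_ratio),
                 spatial_kernel = as.integer(spatial_kernel), combine = combine,
                 batchnorm = isTRUE(batchnorm)),
            class = "ma_config")
}

cbam_build <- function(channels, ratio = 16L, spatial_kernel = 7L) {
  h <- max(1L, channels %/% ratio)
  k <- spatial_kernel
  list(fc1 = list(weight = init_dense(channels, h), bias = numeric(h)),
       fc2 = list(weight = init_dense(h, channels, sd = sqrt(1 / h)), bias = numeric(channels)),
       sconv = list(kernel = init_conv(k, k, 2, 1), bias = numeric(1)))
}

ic_build <- function(cfg) {
  rc <- cfg$reduced_channels
  q <- rc %/% 4L
  conv_bn <- function(k, cin, cout) {
    out <- list(conv = list(kernel = init_conv(k, k, cin, cout),
                            bias = numeric(cout)))
    if (cfg$batchnorm) out$bn <- list(gamma = rep(1, cout), beta = numeric(cout))
    out
  }
  list(b1 = conv_bn(1, rc, q), b3 = conv_bn(3, rc, q), b5 = conv_bn(5, rc, q),
       bp = conv_bn(1, rc, q),
       cbam = cbam_build(rc, cfg$cbam_ratio, cfg$spatial_kernel))
}

ic_stats <- function(cfg) {
  if (!cfg$batchnorm) return(list(b1 = NULL, b3 = NULL, b5 = NULL, bp = NULL))
  q <- cfg$reduced_channels %/% 4L
  bs <- function(c) list(mean = numeric(c), var = rep(1, c))
  list(b1 = bs(q), b3 = bs(q), b5 = bs(q), bp = bs(q))
}

#' Build a multiscale attention block
#'
#' @param cfg An [ma_config()].
#' @param seed Seed for weight initialisation.
#' @return An object of class `ma_block`.
#' @examples
#' ma <- ma_block(ma_config(64, 32), seed = 1)
#' x <- array(rnorm(2 * 4 * 4 * 64), c(2, 4, 4, 64))
#' dim(ma_forward(ma, x)$out)  # 2 4 4 32
#' @export
ma_block <- function(cfg = ma_config(), seed = 1L) {
  stopifnot(inherits(cfg, "ma_config"))
  set.seed(seed)
  rc <- cfg$reduced_channels
  cin_proj <- if (cfg$combine == "concat") 2L * rc else rc
  par <- list(
    reduce = list(conv = list(kernel = init_conv(1, 1, cfg$in_channels, rc),
                              bias = numeric(rc))),
    ic1 = ic_build(cfg),
    ic2 = ic_build(cfg),
    proj = list(conv = list(kernel = init_conv(1, 1, cin_proj, rc),
                            bias = numeric(rc)))
  )
  if (cfg$batchnorm) {
    par$reduce$bn <- list(gamma = rep(1, rc), beta = numeric(rc))
    par$proj$bn <- list(gamma = rep(1, rc), beta = numeric(rc))
  }
  stats <- list(
    reduce = if (cfg$batchnorm) list(mean = numeric(rc), var = rep(1, rc)),
    ic1 = ic_stats(cfg), ic2 = ic_stats(cfg),
    proj = if (cfg$batchnorm) list(mean = numeric(rc), var = rep(1, rc))
  )
  structure(list(cfg = cfg, par = par, stats = stats), class = "ma_block")
}

#' Number of trainable parameters of an MA block
#' @export
ma_param_count <- function(ma) tree_count(ma$par)

#' Zero the IC paths of an MA block
#'
#' Sets every convolution/MLP weight and bias of the two IC paths and the
#' re-projection to zero, reducing the block to the identity on the reduced
#' features (the skip connection alone).
#' @export
ma_ablate_ic <- function(ma) {
  zero <- function(p) {
    for (nm in names(p)) {
      if (is.numeric(p[[nm]])) {
        if (nm %in% c("kernel", "weight", "bias", "beta")) p[[nm]][] <- 0
      } else if (is.list(p[[nm]])) p[[nm]] <- zero(p[[nm]])
    }
    p
  }
  ma$par$ic1 <- zero(ma$par$ic1)
  ma$par$ic2 <- zero(ma$par$ic2)
  ma$par$proj <- zero(ma$par$proj)
  ma
}

# ---- broadcast helpers -----------------------------------------------------

mul_channel_gate <- function(x, gate) {
  d <- dim(x)
  hw <- d[2] * d[3]
  ge <- gate[, rep(seq_len(d[4]), each = hw), drop = FALSE]
  y <- matrix(x, nrow = d[1]) * ge
  dim(y) <- d
  y
}

sum_spatial <- function(x) {   # (B,H,W,C) -> (B,C), summing over H,W
  d <- dim(x)
  hw <- d[2] * d[3]
  m <- matrix(x, nrow = d[1])
  out <- matrix(0, d[1], d[4])
  for (c in seq_len(d[4])) {
    out[, c] <- rowSums(m[, ((c - 1L) * hw + 1L):(c * hw), drop = FALSE])
  }
  out
}

mul_spatial_gate <- function(x, gate) {  # gate (B,H,W,1)
  d <- dim(x)
  y <- as.numeric(x) * rep(as.numeric(gate), times = d[4])
  dim(y) <- d
  y
}

sum_channels <- function(x) {  # (B,H,W,C) -> (B,H,W,1)
  d <- dim(x)
  y <- rowSums(matrix(x, ncol = d[4]))
  dim(y) <- c(d[1], d[2], d[3], 1L)
  y
}

# ---- CBAM ------------------------------------------------------------------

#' Convolutional block attention (channel gate then spatial gate)
#'
#' Channel attention: a shared two-layer MLP applied to the global-average
#' and global-max pooled channel descriptors, summed, passed through a
#' sigmoid and broadcast-multiplied. Spatial attention: a `k x k`
#' convolution over the channel-wise mean and max maps, sigmoid-gated.
#' Both gates lie in (0, 1).
#'
#' @param par A CBAM parameter list (built internally by [ma_block()]).
#' @param x Feature map `[B, H, W, C]`.
#' @return `list(out, cache, gates)`; `gates` holds the channel and spatial
#'   gate values.
#' @export
cbam_forward <- function(par, x, keep_cache = TRUE) {
  d <- dim(x)
  av <- gap_forward(x)
  mx <- gmp_forward(x)
  a1 <- dense_forward(av$out, par$fc1$weight, par$fc1$bias)
  ar <- relu_forward(a1$out)
  a2 <- dense_forward(ar$out, par$fc2$weight, par$fc2$bias)
  m1 <- dense_forward(mx$out, par$fc1$weight, par$fc1$bias)
  mr <- relu_forward(m1$out)
  m2 <- dense_forward(mr$out, par$fc2$weight, par$fc2$bias)
  s <- a2$out + m2$out
  cgate <- sigmoid(s)
  xc <- mul_channel_gate(x, cgate)
  cm <- rowMeans(matrix(xc, ncol = d[4]))
  mm_mat <- matrix(xc, ncol = d[4])
  amax <- max.col(mm_mat, ties.method = "first")
  cmx <- mm_mat[cbind(seq_along(amax), amax)]
  smap <- array(c(cm, cmx), c(d[1], d[2], d[3], 2L))
  sc <- conv2d_forward(smap, par$sconv$kernel, par$sconv$bias, 1L, "same", keep_cache)
  sgate <- sigmoid(sc$out)
  out <- mul_spatial_gate(xc, sgate)
  cache <- if (keep_cache) {
    list(x = x, av = av$cache, mx = mx$cache, a1 = a1$cache, ar = ar$cache,
         a2 = a2$cache, m1 = m1$cache, mr = mr$cache, m2 = m2$cache,
         cgate = cgate, xc = xc, amax = amax, sc = sc$cache, sgate = sgate,
         dims = d)
  } else NULL
  list(out = out, cache = cache, gates = list(channel = cgate, spatial = sgate))
}

#' @noRd
cbam_backward <- function(par, cache, dy) {
  d <- cache$dims
  # spatial gate
  dxc <- mul_spatial_gate(dy, cache$sgate)
  dsgate <- sum_channels(dy * cache$xc)
  dsc <- dsgate * cache$sgate * (1 - cache$sgate)
  bs <- conv2d_backward(dsc, par$sconv$kernel, cache$sc)
  dsmap <- bs$dx
  n <- d[1] * d[2] * d[3]
  dcm <- as.numeric(dsmap[, , , 1L])
  dcmx <- as.numeric(dsmap[, , , 2L])
  # channel mean / max backward into xc
  dxc_extra <- matrix(dcm / d[4], n, d[4])
  dxc_extra[cbind(seq_len(n), cache$amax)] <-
    dxc_extra[cbind(seq_len(n), cache$amax)] + dcmx
  dim(dxc_extra) <- d
  dxc <- dxc + dxc_extra
  # channel gate
  dx <- mul_channel_gate(dxc, cache$cgate)
  dcgate <- sum_spatial(dxc * cache$x)
  ds <- dcgate * cache$cgate * (1 - cache$cgate)
  b_a2 <- dense_backward(ds, par$fc2$weight, cache$a2)
  b_ar <- relu_backward(b_a2$dx, cache$ar)
  b_a1 <- dense_backward(b_ar$dx, par$fc1$weight, cache$a1)
  b_m2 <- dense_backward(ds, par$fc2$weight, cache$m2)
  b_mr <- relu_backward(b_m2$dx, cache$mr)
  b_m1 <- dense_backward(b_mr$dx, par$fc1$weight, cache$m1)
  dx <- dx + gap_backward(b_a1$dx, cache$av)$dx + gmp_backward(b_m1$dx, cache$mx)$dx
  list(dx = dx,
       grads = list(fc1 = list(weight = b_a1$dW + b_m1$dW, bias = b_a1$db + b_m1$db),
                    fc2 = list(weight = b_a2$dW + b_m2$dW, bias = b_a2$db + b_m2$db),
                    sconv = list(kernel = bs$dW, bias = bs$db)))
}

# ---- IC path ---------------------------------------------------------------

#' One IC path: inception multiscale stage followed by CBAM
#'
#' Parallel 1x1, 3x3 and 5x5 convolutions plus a 3x3-maxpool + 1x1 branch,
#' each producing a quarter of the channels, concatenated ('same' padding so
#' the spatial size is preserved), then CBAM attention.
#'
#' @param ma An `ma_block` (whose first IC path parameters are used unless
#'   `which = 2`).
#' @param x Reduced feature map `[B, h, w, reduced_channels]`.
#' @export
ic_forward <- function(ma, x, which = 1L, training = FALSE) {
  nm <- paste0("ic", which)
  r <- ic_forward_impl(ma$par[[nm]], ma$stats[[nm]], x, training, keep_cache = FALSE)
  list(out = r$out, gates = r$gates)
}

ic_forward_impl <- function(par, stats, x, training, keep_cache = TRUE) {
  branch <- function(bpar, bstats, xin) {
    cv <- conv2d_forward(xin, bpar$conv$kernel, bpar$conv$bias, 1L, "same", keep_cache)
    if (!is.null(bpar$bn)) {
      bn <- batchnorm_forward(cv$out, bpar$bn$gamma, bpar$bn$beta,
                              bstats$mean, bstats$var, training)
      rl <- relu_forward(bn$out)
      list(out = rl$out,
           cache = if (keep_cache) list(cv = cv$cache, bn = bn$cache, rl = rl$cache) else NULL,
           stats = list(mean = bn$run_mean, var = bn$run_var))
    } else {
      rl <- relu_forward(cv$out)
      list(out = rl$out,
           cache = if (keep_cache) list(cv = cv$cache, rl = rl$cache) else NULL,
           stats = NULL)
    }
  }
  pool <- maxpool_forward(x, 3L, 1L, padding = 1L, keep_cache = keep_cache)
  r1 <- branch(par$b1, stats$b1, x)
  r3 <- branch(par$b3, stats$b3, x)
  r5 <- branch(par$b5, stats$b5, x)
  rp <- branch(par$bp, stats$bp, pool$out)
  d <- dim(x)
  q <- dim(r1$out)[4]
  u <- array(0, c(d[1], d[2], d[3], 4L * q))
  u[, , , seq_len(q)] <- r1$out
  u[, , , q + seq_len(q)] <- r3$out
  u[, , , 2L * q + seq_len(q)] <- r5$out
  u[, , , 3L * q + seq_len(q)] <- rp$out
  cb <- cbam_forward(par$cbam, u, keep_cache)
  cache <- if (keep_cache) {
    list(pool = pool$cache, r1 = r1$cache, r3 = r3$cache, r5 = r5$cache,
         rp = rp$cache, cb = cb$cache, q = q)
  } else NULL
  list(out = cb$out, cache = cache, gates = cb$gates,
       stats = list(b1 = r1$stats, b3 = r3$stats, b5 = r5$stats, bp = rp$stats))
}

ic_backward_impl <- function(par, cache, dy) {
  cb <- cbam_backward(par$cbam, cache$cb, dy)
  q <- cache$q
  du <- cb$dx
  back_branch <- function(bpar, bcache, dpart) {
    brl <- relu_backward(dpart, bcache$rl)
    if (!is.null(bpar$bn)) {
      bbn <- batchnorm_backward(brl$dx, bcache$bn)
      bcv <- conv2d_backward(bbn$dx, bpar$conv$kernel, bcache$cv)
      list(dx = bcv$dx,
           g = list(conv = list(kernel = bcv$dW, bias = bcv$db),
                    bn = list(gamma = bbn$dgamma, beta = bbn$dbeta)))
    } else {
      bcv <- conv2d_backward(brl$dx, bpar$conv$kernel, bcache$cv)
      list(dx = bcv$dx,
           g = list(conv = list(kernel = bcv$dW, bias = bcv$db)))
    }
  }
  g1 <- back_branch(par$b1, cache$r1, du[, , , seq_len(q), drop = FALSE])
  g3 <- back_branch(par$b3, cache$r3, du[, , , q + seq_len(q), drop = FALSE])
  g5 <- back_branch(par$b5, cache$r5, du[, , , 2L * q + seq_len(q), drop = FALSE])
  gp <- back_branch(par$bp, cache$rp, du[, , , 3L * q + seq_len(q), drop = FALSE])
  dpool <- maxpool_backward(gp$dx, cache$pool)
  dx <- g1$dx + g3$dx + g5$dx + dpool$dx
  list(dx = dx,
       grads = list(b1 = g1$g, b3 = g3$g, b5 = g5$g, bp = gp$g, cbam = cb$grads))
}

# ---- MA block forward/backward --------------------------------------------

#' Run the MA block forward
#'
#' Pipeline: 1x1 reduction (+BN+ReLU) -> two parallel IC paths -> combine
#' (concat or add) -> 1x1 re-projection (+BN) -> add the reduced features
#' (skip connection). Spatial size is preserved; channels go from
#' `in_channels` to `reduced_channels`.
#'
#' @param ma An [ma_block()].
#' @param x Feature map `[B, h, w, in_channels]`.
#' @param training Use batch statistics and keep backward caches.
#' @return `list(out, cache, ma)` where `out` is `[B, h, w, reduced_channels]`.
#' @export
ma_forward <- function(ma, x, training = FALSE, keep_cache = training) {
  cfg <- ma$cfg
  d <- dim(x)
  if (length(d) != 4L) stop("expected a [B, h, w, C] feature map")
  if (d[4] != cfg$in_channels) {
    stop("channel mismatch: feature map has ", d[4], " channels, MA expects ",
         cfg$in_channels)
  }
  cv <- conv2d_forward(x, ma$par$reduce$conv$kernel, ma$par$reduce$conv$bias,
                       1L, "same", keep_cache)
  if (!is.null(ma$par$reduce$bn)) {
    bn <- batchnorm_forward(cv$out, ma$par$reduce$bn$gamma, ma$par$reduce$bn$beta,
                            ma$stats$reduce$mean, ma$stats$reduce$var, training)
    rl <- relu_forward(bn$out)
    bn_cache <- bn$cache
    ma$stats$reduce <- list(mean = bn$run_mean, var = bn$run_var)
  } else {
    rl <- relu_forward(cv$out)
    bn_cache <- NULL
  }
  r <- rl$out
  i1 <- ic_forward_impl(ma$par$ic1, ma$stats$ic1, r, training, keep_cache)
  i2 <- ic_forward_impl(ma$par$ic2, ma$stats$ic2, r, training, keep_cache)
  ma$stats$ic1 <- i1$stats
  ma$stats$ic2 <- i2$stats
  rc <- cfg$reduced_channels
  if (cfg$combine == "concat") {
    comb <- array(0, c(d[1], d[2], d[3], 2L * rc))
    comb[, , , seq_len(rc)] <- i1$out
    comb[, , , rc + seq_len(rc)] <- i2$out
  } else {
    comb <- i1$out + i2$out
  }
  pj <- conv2d_forward(comb, ma$par$proj$conv$kernel, ma$par$proj$conv$bias,
                       1L, "same", keep_cache)
  if (!is.null(ma$par$proj$bn)) {
    pb <- batchnorm_forward(pj$out, ma$par$proj$bn$gamma, ma$par$proj$bn$beta,
                            ma$stats$proj$mean, ma$stats$proj$var, training)
    ma$stats$proj <- list(mean = pb$run_mean, var = pb$run_var)
    pre <- pb$out
    pb_cache <- pb$cache
  } else {
    pre <- pj$out
    pb_cache <- NULL
  }
  out <- pre + r
  attr(out, "stage") <- "ma"
  attr(out, "branch") <- attr(x, "branch")
  cache <- if (keep_cache) {
    list(cv = cv$cache, bn = bn_cache, rl = rl$cache, i1 = i1$cache,
         i2 = i2$cache, pj = pj$cache, pb = pb_cache, dims = d)
  } else NULL
  list(out = out, cache = cache, ma = ma)
}

#' @noRd
ma_backward <- function(ma, cache, dy) {
  cfg <- ma$cfg
  rc <- cfg$reduced_channels
  if (!is.null(cache$pb)) {
    bpb <- batchnorm_backward(dy, cache$pb)
    dproj_pre <- bpb$dx
  } else {
    bpb <- NULL
    dproj_pre <- dy
  }
  bpj <- conv2d_backward(dproj_pre, ma$par$proj$conv$kernel, cache$pj)
  if (cfg$combine == "concat") {
    d1 <- bpj$dx[, , , seq_len(rc), drop = FALSE]
    d2 <- bpj$dx[, , , rc + seq_len(rc), drop = FALSE]
  } else {
    d1 <- bpj$dx
    d2 <- bpj$dx
  }
  bi1 <- ic_backward_impl(ma$par$ic1, cache$i1, d1)
  bi2 <- ic_backward_impl(ma$par$ic2, cache$i2, d2)
  dr <- dy + bi1$dx + bi2$dx      # skip connection + both IC paths
  brl <- relu_backward(dr, cache$rl)
  reduce_g <- list()
  if (!is.null(cache$bn)) {
    bbn <- batchnorm_backward(brl$dx, cache$bn)
    bcv <- conv2d_backward(bbn$dx, ma$par$reduce$conv$kernel, cache$cv)
    reduce_g$bn <- list(gamma = bbn$dgamma, beta = bbn$dbeta)
  } else {
    bcv <- conv2d_backward(brl$dx, ma$par$reduce$conv$kernel, cache$cv)
  }
  reduce_g$conv <- list(kernel = bcv$dW, bias = bcv$db)
  proj_g <- list(conv = list(kernel = bpj$dW, bias = bpj$db))
  if (!is.null(bpb)) proj_g$bn <- list(gamma = bpb$dgamma, beta = bpb$dbeta)
  list(dx = bcv$dx,
       dr = dr,
       grads = list(reduce = reduce_g, ic1 = bi1$grads, ic2 = bi2$grads,
                    proj = proj_g))
}
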