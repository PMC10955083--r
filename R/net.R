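# Sequential network machinery used by the backbone extractors. A net is a
# plain list of layer specs; each layer is a list with a `type`, a `par` list
# holding trainable arrays (names "kernel"/"weight" are L1-penalised) and,
# for batchnorm, a `stats` list with running moments. net_forward returns the
# (possibly stats-updated) net alongside the output so running moments
# propagate functionally.

layer_conv <- function(kh, kw, cin, cout, stride = 1L, padding = "same",
                       bias = TRUE) {
  list(type = "conv", stride = as.integer(stride), padding = padding,
       par = list(kernel = init_conv(kh, kw, cin, cout),
                  bias = if (bias) numeric(cout) else NULL))
}

layer_bn <- function(c) {
  list(type = "bn",
       par = list(gamma = rep(1, c), beta = numeric(c)),
       stats = list(mean = numeric(c), var = rep(1, c)))
}

layer_relu <- function() list(type = "relu", par = list())

layer_maxpool <- function(k, stride = k, padding = 0L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       padding = as.integer(padding), par = list())
}

layer_avgpool <- function(k, stride = k) {
  list(type = "avgpool", k = as.integer(k), stride = as.integer(stride),
       par = list())
}

# One dense-connectivity layer: BN-ReLU-1x1 conv (bottleneck), BN-ReLU-3x3
# conv (growth channels), output concatenated to the input along channels.
layer_dense_unit <- function(cin, growth = 32L, bottleneck = 4L) {
  bc <- bottleneck * growth
  list(type = "dense_unit",
       par = list(bn1 = layer_bn(cin)$par,
                  conv1 = list(kernel = init_conv(1, 1, cin, bc), bias = numeric(bc)),
                  bn2 = layer_bn(bc)$par,
                  conv2 = list(kernel = init_conv(3, 3, bc, growth), bias = numeric(growth))),
       stats = list(bn1 = list(mean = numeric(cin), var = rep(1, cin)),
                    bn2 = list(mean = numeric(bc), var = rep(1, bc))))
}

# Residual bottleneck (1x1 -> 3x3 -> 1x1, expansion 4) with optional
# projection shortcut carrying the stride.
layer_bottleneck <- function(cin, width, stride = 1L) {
  cout <- 4L * width
  proj <- (stride != 1L || cin != cout)
  par <- list(conv1 = list(kernel = init_conv(1, 1, cin, width), bias = numeric(width)),
              bn1 = layer_bn(width)$par,
              conv2 = list(kernel = init_conv(3, 3, width, width), bias = numeric(width)),
              bn2 = layer_bn(width)$par,
              conv3 = list(kernel = init_conv(1, 1, width, cout), bias = numeric(cout)),
              bn3 = layer_bn(cout)$par)
  stats <- list(bn1 = list(mean = numeric(width), var = rep(1, width)),
                bn2 = list(mean = numeric(width), var = rep(1, width)),
                bn3 = list(mean = numeric(cout), var = rep(1, cout)))
  if (proj) {
    par$proj <- list(kernel = init_conv(1, 1, cin, cout), bias = numeric(cout))
    par$bnp <- layer_bn(cout)$par
    stats$bnp <- list(mean = numeric(cout), var = rep(1, cout))
  }
  list(type = "bottleneck", stride = as.integer(stride), proj = proj, par = par,
       stats = stats)
}

# Depthwise-separable convolution (depthwise 3x3 then pointwise 1x1).
layer_sepconv <- function(cin, cout) {
  list(type = "sepconv",
       par = list(kernel = array(stats::rnorm(3 * 3 * cin, sd = sqrt(2 / 9)), c(3, 3, cin)),
                  point = list(kernel = init_conv(1, 1, cin, cout), bias = numeric(cout))))
}

# Depthwise conv forward/backward; reuses the pooling index plan, whose rows
# enumerate (batch, out_row, out_col, channel) and columns the spatial taps.
dwconv_forward <- function(x, W, keep_cache = TRUE) {
  d <- dim(x)
  k <- dim(W)[1]
  p <- same_pad(k)
  plan <- pool_index_plan(d[1], d[2], d[3], d[4], k, 1L, p, p)
  xp <- pad_nhwc(x, p, p)
  m <- matrix(xp[as.vector(outer(plan$base, plan$off, "+"))], nrow = length(plan$base))
  nblk <- d[1] * plan$OH * plan$OW
  y <- numeric(length(plan$base))
  wm <- matrix(W, nrow = k * k)   # (k*k) x C
  for (c in seq_len(d[4])) {
    rows <- ((c - 1L) * nblk + 1L):(c * nblk)
    y[rows] <- m[rows, , drop = FALSE] %*% wm[, c]
  }
  dim(y) <- c(d[1], plan$OH, plan$OW, d[4])
  cache <- if (keep_cache) list(m = m, plan = plan, dims = d, k = k, p = p) else NULL
  list(out = y, cache = cache)
}

dwconv_backward <- function(dy, W, cache) {
  d <- cache$dims
  k <- cache$k
  plan <- cache$plan
  nblk <- d[1] * plan$OH * plan$OW
  wm <- matrix(W, nrow = k * k)
  dyv <- as.numeric(dy)
  dW <- matrix(0, k * k, d[4])
  dxp <- numeric(d[1] * plan$Hp * plan$Wp * d[4])
  for (c in seq_len(d[4])) {
    rows <- ((c - 1L) * nblk + 1L):(c * nblk)
    dblk <- dyv[rows]
    dW[, c] <- crossprod(cache$m[rows, , drop = FALSE], dblk)
    dmc <- tcrossprod(dblk, wm[, c])    # nblk x k*k
    base <- plan$base[rows]
    for (q in seq_along(plan$off)) {
      idx <- base + plan$off[q]
      dxp[idx] <- dxp[idx] + dmc[, q]
    }
  }
  dim(dxp) <- c(d[1], plan$Hp, plan$Wp, d[4])
  p <- cache$p
  dx <- if (p > 0L) dxp[, p + seq_len(d[2]), p + seq_len(d[3]), , drop = FALSE] else dxp
  dim(dW) <- c(k, k, d[4])
  list(dx = dx, dW = dW)
}

bn_apply <- function(x, par, stats, training, keep_cache = TRUE) {
  r <- batchnorm_forward(x, par$gamma, par$beta, stats$mean, stats$var, training)
  list(out = r$out, cache = if (keep_cache) r$cache else NULL,
       stats = list(mean = r$run_mean, var = r$run_var))
}

net_forward <- function(net, x, training = FALSE, keep_cache = training) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    l <- net[[i]]
    r <- switch(l$type,
      conv = conv2d_forward(x, l$par$kernel, l$par$bias, l$stride, l$padding,
                            keep_cache = keep_cache),
      bn = {
        rr <- bn_apply(x, l$par, l$stats, training, keep_cache)
        net[[i]]$stats <- rr$stats
        rr
      },
      relu = relu_forward(x),
      maxpool = maxpool_forward(x, l$k, l$stride, l$padding, keep_cache = keep_cache),
      avgpool = avgpool_forward(x, l$k, l$stride, keep_cache = keep_cache),
      dense_unit = {
        rr <- dense_unit_forward(l, x, training, keep_cache)
        net[[i]]$stats <- rr$stats
        rr
      },
      bottleneck = {
        rr <- bottleneck_forward(l, x, training, keep_cache)
        net[[i]]$stats <- rr$stats
        rr
      },
      sepconv = sepconv_forward(l, x, keep_cache),
      stop("unknown layer type: ", l$type)
    )
    x <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(out = x, caches = caches, net = net)
}

net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  dy <- dout
  for (i in rev(seq_along(net))) {
    l <- net[[i]]
    cc <- caches[[i]]
    r <- switch(l$type,
      conv = {
        b <- conv2d_backward(dy, l$par$kernel, cc)
        list(dx = b$dx, g = list(kernel = b$dW, bias = b$db))
      },
      bn = {
        b <- batchnorm_backward(dy, cc)
        list(dx = b$dx, g = list(gamma = b$dgamma, beta = b$dbeta))
      },
      relu = list(dx = relu_backward(dy, cc)$dx, g = NULL),
      maxpool = list(dx = maxpool_backward(dy, cc)$dx, g = NULL),
      avgpool = list(dx = avgpool_backward(dy, cc)$dx, g = NULL),
      dense_unit = dense_unit_backward(l, cc, dy),
      bottleneck = bottleneck_backward(l, cc, dy),
      sepconv = sepconv_backward(l, cc, dy),
      stop("unknown layer type: ", l$type)
    )
    dy <- r$dx
    grads[i] <- list(r$g)       # keep NULL placeholders for param-free layers
  }
  list(dx = dy, grads = grads)
}

dense_unit_forward <- function(l, x, training, keep_cache) {
  cin <- dim(x)[4]
  b1 <- bn_apply(x, l$par$bn1, l$stats$bn1, training, keep_cache)
  r1 <- relu_forward(b1$out)
  c1 <- conv2d_forward(r1$out, l$par$conv1$kernel, l$par$conv1$bias, 1L, "same", keep_cache)
  b2 <- bn_apply(c1$out, l$par$bn2, l$stats$bn2, training, keep_cache)
  r2 <- relu_forward(b2$out)
  c2 <- conv2d_forward(r2$out, l$par$conv2$kernel, l$par$conv2$bias, 1L, "same", keep_cache)
  d <- dim(x)
  g <- dim(c2$out)[4]
  out <- array(0, c(d[1], d[2], d[3], cin + g))
  out[, , , seq_len(cin)] <- x
  out[, , , cin + seq_len(g)] <- c2$out
  cache <- if (keep_cache) {
    list(b1 = b1$cache, r1 = r1$cache, c1 = c1$cache, b2 = b2$cache,
         r2 = r2$cache, c2 = c2$cache, cin = cin, g = g)
  } else NULL
  list(out = out, cache = cache,
       stats = list(bn1 = b1$stats, bn2 = b2$stats))
}

dense_unit_backward <- function(l, cc, dy) {
  cin <- cc$cin
  g <- cc$g
  dx_pass <- dy[, , , seq_len(cin), drop = FALSE]
  dnew <- dy[, , , cin + seq_len(g), drop = FALSE]
  bc2 <- conv2d_backward(dnew, l$par$conv2$kernel, cc$c2)
  br2 <- relu_backward(bc2$dx, cc$r2)
  bb2 <- batchnorm_backward(br2$dx, cc$b2)
  bc1 <- conv2d_backward(bb2$dx, l$par$conv1$kernel, cc$c1)
  br1 <- relu_backward(bc1$dx, cc$r1)
  bb1 <- batchnorm_backward(br1$dx, cc$b1)
  list(dx = dx_pass + bb1$dx,
       g = list(bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
                conv1 = list(kernel = bc1$dW, bias = bc1$db),
                bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta),
                conv2 = list(kernel = bc2$dW, bias = bc2$db)))
}

bottleneck_forward <- function(l, x, training, keep_cache) {
  c1 <- conv2d_forward(x, l$par$conv1$kernel, l$par$conv1$bias, 1L, "same", keep_cache)
  b1 <- bn_apply(c1$out, l$par$bn1, l$stats$bn1, training, keep_cache)
  r1 <- relu_forward(b1$out)
  c2 <- conv2d_forward(r1$out, l$par$conv2$kernel, l$par$conv2$bias, l$stride, "same", keep_cache)
  b2 <- bn_apply(c2$out, l$par$bn2, l$stats$bn2, training, keep_cache)
  r2 <- relu_forward(b2$out)
  c3 <- conv2d_forward(r2$out, l$par$conv3$kernel, l$par$conv3$bias, 1L, "same", keep_cache)
  b3 <- bn_apply(c3$out, l$par$bn3, l$stats$bn3, training, keep_cache)
  stats <- list(bn1 = b1$stats, bn2 = b2$stats, bn3 = b3$stats)
  if (l$proj) {
    cp <- conv2d_forward(x, l$par$proj$kernel, l$par$proj$bias, l$stride, "same", keep_cache)
    bp <- bn_apply(cp$out, l$par$bnp, l$stats$bnp, training, keep_cache)
    stats$bnp <- bp$stats
    short <- bp$out
  } else {
    cp <- NULL; bp <- NULL
    short <- x
  }
  pre <- b3$out + short
  ro <- relu_forward(pre)
  cache <- if (keep_cache) {
    list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache, c2 = c2$cache,
         b2 = b2$cache, r2 = r2$cache, c3 = c3$cache, b3 = b3$cache,
         cp = if (l$proj) cp$cache else NULL, bp = if (l$proj) bp$cache else NULL,
         ro = ro$cache)
  } else NULL
  list(out = ro$out, cache = cache, stats = stats)
}

bottleneck_backward <- function(l, cc, dy) {
  dpre <- relu_backward(dy, cc$ro)$dx
  bb3 <- batchnorm_backward(dpre, cc$b3)
  bc3 <- conv2d_backward(bb3$dx, l$par$conv3$kernel, cc$c3)
  br2 <- relu_backward(bc3$dx, cc$r2)
  bb2 <- batchnorm_backward(br2$dx, cc$b2)
  bc2 <- conv2d_backward(bb2$dx, l$par$conv2$kernel, cc$c2)
  br1 <- relu_backward(bc2$dx, cc$r1)
  bb1 <- batchnorm_backward(br1$dx, cc$b1)
  bc1 <- conv2d_backward(bb1$dx, l$par$conv1$kernel, cc$c1)
  g <- list(conv1 = list(kernel = bc1$dW, bias = bc1$db),
            bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
            conv2 = list(kernel = bc2$dW, bias = bc2$db),
            bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta),
            conv3 = list(kernel = bc3$dW, bias = bc3$db),
            bn3 = list(gamma = bb3$dgamma, beta = bb3$dbeta))
  if (l$proj) {
    bbp <- batchnorm_backward(dpre, cc$bp)
    bcp <- conv2d_backward(bbp$dx, l$par$proj$kernel, cc$cp)
    g$proj <- list(kernel = bcp$dW, bias = bcp$db)
    g$bnp <- list(gamma = bbp$dgamma, beta = bbp$dbeta)
    dx <- bc1$dx + bcp$dx
  } else {
    dx <- bc1$dx + dpre
  }
  list(dx = dx, g = g)
}

sepconv_forward <- function(l, x, keep_cache) {
  dw <- dwconv_forward(x, l$par$kernel, keep_cache)
  pw <- conv2d_forward(dw$out, l$par$point$kernel, l$par$point$bias, 1L, "same", keep_cache)
  cache <- if (keep_cache) list(dw = dw$cache, pw = pw$cache) else NULL
  list(out = pw$out, cache = cache)
}

sepconv_backward <- function(l, cc, dy) {
  bp <- conv2d_backward(dy, l$par$point$kernel, cc$pw)
  bd <- dwconv_backward(bp$dx, l$par$kernel, cc$dw)
  list(dx = bd$dx,
       g = list(kernel = bd$dW,
                point = list(kernel = bp$dW, bias = bp$db)))
}

net_param_count <- function(net) {
  sum(vapply(net, function(l) tree_count(l$par), numeric(1)))
}

net_update <- function(net, grads, lr, l1 = 0, momentum = 0, vel = NULL) {
  if (is.null(vel)) vel <- vector("list", length(net))
  for (i in seq_along(net)) {
    if (!is.null(grads[[i]]) && length(net[[i]]$par)) {
      r <- tree_sgd(net[[i]]$par, grads[[i]], lr, l1, momentum, vel[[i]])
      net[[i]]$par <- r$par
      vel[i] <- list(r$vel)
    }
  }
  list(net = net, vel = vel)
}

net_l1 <- function(net) sum(vapply(net, function(l) tree_l1(l$par), numeric(1)))
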