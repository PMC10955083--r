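test_that("MA block maps [B,h,w,in] to [B,h,w,in/2] and validates channels", {
  ma <- ma_block(ma_config(64L, 32L), seed = 1L)
  x <- array(rnorm(2 * 4 * 4 * 64), c(2, 4, 4, 64))
  out <- ma_forward(ma, x)$out
  expect_equal(dim(out), c(2L, 4L, 4L, 32L))
  expect_true(all(is.finite(out)))
  expect_error(ma_forward(ma, array(0, c(2, 4, 4, 16))), "channel mismatch")
  expect_error(ma_config(64L, 30L), "divisible by 4")
})

test_that("parameter count matches the closed-form layer-by-layer sum", {
  # in = 64, reduced = 32, cbam ratio 16, spatial kernel 7, concat combine
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  bn_p <- function(c) 2 * c
  q <- 32 / 4
  h <- max(1, 32 %/% 16)
  ic_p <- conv_p(1, 32, q) + bn_p(q) +      # 1x1 branch
    conv_p(3, 32, q) + bn_p(q) +            # 3x3 branch
    conv_p(5, 32, q) + bn_p(q) +            # 5x5 branch
    conv_p(1, 32, q) + bn_p(q) +            # pool + 1x1 branch
    (32 * h + h) + (h * 32 + 32) +          # shared CBAM MLP
    conv_p(7, 2, 1)                         # spatial-attention conv
  expected <- conv_p(1, 64, 32) + bn_p(32) +      # reduction
    2 * ic_p +                                    # two IC paths
    conv_p(1, 2 * 32, 32) + bn_p(32)              # re-projection
  ma <- ma_block(ma_config(64L, 32L), seed = 2L)
  expect_equal(ma_param_count(ma), expected)
  # norm-free variant drops exactly the batchnorm parameters
  ma_nf <- ma_block(ma_config(64L, 32L, batchnorm = FALSE), seed = 2L)
  expect_equal(ma_param_count(ma_nf),
               expected - bn_p(32) * 2 - 2 * 4 * bn_p(q))
})

test_that("zeroed IC paths reduce the MA block to the skip connection", {
  for (bn in c(TRUE, FALSE)) {
    ma <- ma_ablate_ic(ma_block(ma_config(16L, 8L, cbam_ratio = 2L,
                                          batchnorm = bn), seed = 3L))
    x <- array(rnorm(2 * 3 * 3 * 16), c(2, 3, 3, 16))
    fw <- ma_forward(ma, x, training = TRUE)
    # reduced features = ReLU((BN)(1x1 conv)); recompute them directly
    cv <- mpfusion:::conv2d_forward(x, ma$par$reduce$conv$kernel,
                                    ma$par$reduce$conv$bias, 1L, "same")
    r <- if (bn) {
      b <- mpfusion:::batchnorm_forward(cv$out, ma$par$reduce$bn$gamma,
                                        ma$par$reduce$bn$beta,
                                        numeric(8), rep(1, 8), TRUE)
      pmax(b$out, 0)
    } else pmax(cv$out, 0)
    expect_equal(fw$out, r, ignore_attr = TRUE)
    # gradient flows through the skip path untouched
    dy <- array(rnorm(length(fw$out)), dim(fw$out))
    bw <- mpfusion:::ma_backward(fw$ma, fw$cache, dy)
    expect_equal(bw$dr, dy, tolerance = 1e-12)
  }
})

test_that("CBAM gates live in (0,1) and zero weights give exactly x/4", {
  ma <- ma_block(tiny_ma_config(), seed = 4L)
  x <- array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
  cb <- cbam_forward(ma$par$ic1$cbam, x)
  expect_true(all(cb$gates$channel > 0 & cb$gates$channel < 1))
  expect_true(all(cb$gates$spatial > 0 & cb$gates$spatial < 1))
  # hand-built zero parameters: both pre-activations are 0, sigmoid = 0.5
  zero_par <- list(fc1 = list(weight = matrix(0, 4, 2), bias = numeric(2)),
                   fc2 = list(weight = matrix(0, 2, 4), bias = numeric(4)),
                   sconv = list(kernel = array(0, c(3, 3, 2, 1)), bias = 0))
  cb0 <- cbam_forward(zero_par, x)
  expect_equal(cb0$out, x / 4, tolerance = 1e-12)
})

test_that("CBAM gate values match scalar sigmoid arithmetic on a toy map", {
  # 1 batch, 2x2 spatial, 2 channels, hand-set shared MLP (hidden width 1)
  x <- array(c(1, 2, 3, 4, -1, 0, 1, 2) / 4, c(1, 2, 2, 2))
  par <- list(fc1 = list(weight = matrix(c(0.5, -0.25), 2, 1), bias = 0.1),
              fc2 = list(weight = matrix(c(1, -1), 1, 2), bias = c(0, 0.2)),
              sconv = list(kernel = array(0, c(3, 3, 2, 1)), bias = 0.4))
  avg <- apply(x, c(1, 4), mean)
  mx <- apply(x, c(1, 4), max)
  mlp <- function(v) {
    hidden <- max(0, sum(v * par$fc1$weight) + par$fc1$bias)
    hidden * par$fc2$weight[1, ] + par$fc2$bias
  }
  cgate <- 1 / (1 + exp(-(mlp(avg[1, ]) + mlp(mx[1, ]))))
  sgate <- 1 / (1 + exp(-0.4))              # zero spatial kernel, bias 0.4
  manual <- x
  for (c in 1:2) manual[1, , , c] <- x[1, , , c] * cgate[c] * sgate
  cb <- cbam_forward(par, x)
  expect_equal(as.numeric(cb$gates$channel), as.numeric(cgate), tolerance = 1e-12)
  expect_equal(cb$out, manual, tolerance = 1e-12)
})

test_that("on a single-pixel map the 3x3/5x5 branches reduce to centre taps", {
  cfg <- tiny_ma_config(batchnorm = FALSE)
  ma <- ma_block(cfg, seed = 5L)
  x1 <- array(rnorm(2 * 1 * 1 * 4), c(2, 1, 1, 4))
  full <- ic_forward(ma, x1, which = 1L)$out
  # zero every non-centre tap: output must be unchanged under 'same' padding
  ma2 <- ma
  k3 <- ma2$par$ic1$b3$conv$kernel
  k3[-2, , , ] <- 0; k3[, -2, , ] <- 0
  k3[2, 2, , ] <- ma$par$ic1$b3$conv$kernel[2, 2, , ]
  ma2$par$ic1$b3$conv$kernel <- k3
  k5 <- array(0, dim(ma2$par$ic1$b5$conv$kernel))
  k5[3, 3, , ] <- ma$par$ic1$b5$conv$kernel[3, 3, , ]
  ma2$par$ic1$b5$conv$kernel <- k5
  expect_equal(ic_forward(ma2, x1, which = 1L)$out, full, tolerance = 1e-12)
  # and the centre-tap arithmetic itself, by hand, for the 3x3 branch
  w <- ma$par$ic1$b3$conv$kernel[2, 2, , 1]
  b <- ma$par$ic1$b3$conv$bias[1]
  manual <- pmax(x1[1, 1, 1, ] %*% w + b, 0)
  cv <- mpfusion:::conv2d_forward(x1, ma$par$ic1$b3$conv$kernel,
                                  ma$par$ic1$b3$conv$bias, 1L, "same")
  expect_equal(pmax(cv$out[1, 1, 1, 1], 0), as.numeric(manual), tolerance = 1e-12)
})

test_that("MA backward matches finite differences on a tiny instance", {
  for (bn in c(TRUE, FALSE)) {
    ma <- ma_block(tiny_ma_config(batchnorm = bn), seed = 6L)
    x <- array(rnorm(2 * 3 * 3 * 8), c(2, 3, 3, 8))
    set.seed(1)
    dy <- array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
    fw <- ma_forward(ma, x, training = TRUE)
    bw <- mpfusion:::ma_backward(fw$ma, fw$cache, dy)
    f <- function(xx) sum(ma_forward(ma, xx, training = TRUE)$out * dy)
    expect_lt(max(abs(bw$dx - num_grad(f, x))), 1e-6)
    # one weight leaf per structural element
    g <- bw$grads$ic1$cbam$fc1$weight
    p0 <- ma$par$ic1$cbam$fc1$weight
    fw_leaf <- function(pp) {
      ma2 <- ma
      ma2$par$ic1$cbam$fc1$weight <- pp
      sum(ma_forward(ma2, x, training = TRUE)$out * dy)
    }
    expect_lt(max(abs(g - num_grad(fw_leaf, p0))), 1e-6)
  }
})

test_that("MA attaches to the compact backbone (plug-and-play channels)", {
  ex <- build_extractor("compact_test", seed = 7L)
  x <- array(runif(2 * 32 * 32 * 3), c(2, 32, 32, 3))
  fmap <- extractor_forward(ex, x)$out
  ma <- ma_block(ma_config(64L, 32L, batchnorm = FALSE), seed = 7L)
  out <- ma_forward(ma, fmap)$out
  expect_equal(dim(out), c(2L, 1L, 1L, 32L))
  # 'add' combine preserves the contract too
  ma_add <- ma_block(ma_config(64L, 32L, combine = "add", batchnorm = FALSE),
                     seed = 7L)
  expect_equal(dim(ma_forward(ma_add, fmap)$out), c(2L, 1L, 1L, 32L))
})
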