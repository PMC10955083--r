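# Independent naive-loop oracle for the whole fusion head: scalar loops
# only, no vectorised primitives shared with the implementation.
naive_saff <- function(head, ta, tb) {
  d <- head$d
  B <- dim(ta)[1]
  mm <- function(A, Bm) {
    C <- matrix(0, nrow(A), ncol(Bm))
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(Bm))) {
      s <- 0
      for (k in seq_len(ncol(A))) s <- s + A[i, k] * Bm[k, j]
      C[i, j] <- s
    }
    C
  }
  out <- list(probs = matrix(0, B, 2), g = array(0, c(B, 3, 3)),
              f = array(0, c(B, 3, d)), h = array(0, c(B, 3, d)))
  for (b in seq_len(B)) {
    Tk <- rbind(ta[b, 1, ], tb[b, 1, ], head$par$cls)
    Q <- mm(Tk, head$par$q$weight)
    K <- mm(Tk, head$par$k$weight)
    V <- mm(Tk, head$par$v$weight)
    S <- mm(Q, t(K)) / sqrt(d)
    g <- matrix(0, 3, 3)
    for (i in 1:3) {
      e <- exp(S[i, ] - max(S[i, ]))
      g[i, ] <- e / sum(e)
    }
    f <- mm(g, V)
    h <- head$par$theta * V + f
    p <- c(as.vector(g), as.vector(h))
    z1 <- as.vector(mm(matrix(p, 1), head$par$fc1$weight)) + head$par$fc1$bias
    z2 <- as.vector(mm(matrix(pmax(z1, 0), 1), head$par$fc2$weight)) +
      head$par$fc2$bias
    e <- exp(z2 - max(z2))
    out$probs[b, ] <- e / sum(e)
    out$g[b, , ] <- g
    out$f[b, , ] <- f
    out$h[b, , ] <- h
  }
  out
}

test_that("pooling to tokens averages the spatial axes exactly", {
  const <- array(2.5, c(3, 7, 7, 6))
  tok <- pool_and_tokenize(const)
  expect_equal(dim(tok), c(3L, 1L, 6L))
  expect_true(all(tok == 2.5))
  # hand-filled 2x2 spatial toy: token = mean of the four numbers
  toy <- array(0, c(1, 2, 2, 2))
  toy[1, , , 1] <- c(1, 2, 3, 4)
  toy[1, , , 2] <- c(10, 20, 30, 40)
  tk <- pool_and_tokenize(toy)
  expect_equal(as.numeric(tk[1, 1, ]), c(2.5, 25))
  big <- pool_and_tokenize(array(rnorm(8 * 7 * 7 * 512), c(8, 7, 7, 512)))
  expect_equal(dim(big), c(8L, 1L, 512L))
})

test_that("token assembly fixes the (A, B, cls) order and broadcasts cls", {
  ta <- array(1, c(2, 1, 4))
  tb <- array(2, c(2, 1, 4))
  cls <- c(9, 8, 7, 6)
  bundle <- assemble_tokens(ta, tb, cls)
  expect_equal(dim(bundle), c(2L, 3L, 4L))
  expect_true(all(bundle[, 1, ] == 1))
  expect_true(all(bundle[, 2, ] == 2))
  expect_equal(bundle[1, 3, ], cls)
  expect_equal(bundle[2, 3, ], cls)
  one <- assemble_tokens(array(0, c(1, 1, 4)), array(0, c(1, 1, 4)), cls)
  expect_equal(dim(one), c(1L, 3L, 4L))
  swapped <- assemble_tokens(tb, ta, cls)
  expect_equal(swapped[, 1, ], bundle[, 2, ])
  expect_equal(swapped[, 2, ], bundle[, 1, ])
  expect_equal(swapped[, 3, ], bundle[, 3, ])
  expect_error(assemble_tokens(ta, array(0, c(2, 1, 5)), cls), "mismatch")
})

test_that("attention rows are simplex weights; zero projections give 1/3", {
  set.seed(1)
  Q <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  K <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  g <- attention_matrix(Q, K)
  expect_equal(apply(g, c(1, 2), sum), matrix(1, 2, 3), tolerance = 1e-12)
  expect_true(all(g > 0 & g < 1))
  g0 <- attention_matrix(array(0, c(2, 3, 4)), array(0, c(2, 3, 4)))
  expect_true(all(abs(g0 - 1 / 3) < 1e-12))
})

test_that("d = 2 toy attention matches a hand softmax", {
  # tokens [[1,0],[0,1],[1,1]], Wq = Wk = I
  Tk <- rbind(c(1, 0), c(0, 1), c(1, 1))
  Q <- array(0, c(1, 3, 2)); Q[1, , ] <- Tk
  g <- attention_matrix(Q, Q, d = 2)
  S <- Tk %*% t(Tk) / sqrt(2)
  manual <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(g[1, , ], manual, tolerance = 1e-12)
})

test_that("common features obey the residual identity and convexity", {
  set.seed(2)
  g <- array(1 / 3, c(2, 3, 3))
  v <- c(1, -2, 0.5, 4)
  V <- array(0, c(2, 3, 4))
  for (i in 1:3) V[, i, ] <- rep(v, each = 2)
  cf <- common_features(g, V, theta = 0)
  expect_equal(cf$h, cf$f)                          # theta = 0 limit
  for (i in 1:3) expect_equal(cf$f[1, i, ], v)      # convex combination
  # 3x2 toy against a triple-loop multiply
  g1 <- matrix(runif(9), 3); g1 <- g1 / rowSums(g1)
  V1 <- matrix(rnorm(6), 3, 2)
  G <- array(0, c(1, 3, 3)); G[1, , ] <- g1
  Vv <- array(0, c(1, 3, 2)); Vv[1, , ] <- V1
  cf2 <- common_features(G, Vv, theta = 0.3)
  manual_f <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) for (k in 1:3) {
    manual_f[i, j] <- manual_f[i, j] + g1[i, k] * V1[k, j]
  }
  expect_equal(cf2$f[1, , ], manual_f, tolerance = 1e-12)
  expect_equal(cf2$h[1, , ], 0.3 * V1 + manual_f, tolerance = 1e-12)
  expect_error(common_features(G, Vv, theta = -1), "nonnegative")
})

test_that("fused vector lengths follow the readout mode", {
  g <- array(1 / 3, c(2, 3, 3))
  h <- array(0, c(2, 3, 512))
  expect_equal(ncol(fuse_features(g, h, "full")), 3L * 512L + 9L)  # 1545
  expect_equal(ncol(fuse_features(g, h, "cls")), 512L + 3L)        # 515
  expect_error(fuse_features(g, h, "both"), "arg")
  # zero tokens, theta = 0: p = (flattened uniform g, zeros)
  head <- saff_head(d = 4, theta = 0, hidden = 3, seed = 1)
  head$par$cls[] <- 0
  z <- array(0, c(1, 1, 4))
  fw <- saff_forward(head, z, z)
  expect_equal(fw$p[1, 1:9], rep(1 / 3, 9), tolerance = 1e-12)
  expect_equal(fw$p[1, 10:21], rep(0, 12), tolerance = 1e-12)
})

test_that("classifier emits softmax distributions; zero weights give 0.5", {
  head <- saff_head(d = 4, hidden = 3, seed = 2)
  p <- matrix(rnorm(10 * 21), 10)
  probs <- classify_fused(head, p)
  expect_equal(rowSums(probs), rep(1, 10), tolerance = 1e-12)
  head0 <- head
  head0$par$fc1$weight[] <- 0; head0$par$fc1$bias[] <- 0
  head0$par$fc2$weight[] <- 0; head0$par$fc2$bias[] <- 0
  expect_true(all(abs(classify_fused(head0, p) - 0.5) < 1e-12))
  # hand-set 2x2 final layer on a length-2 fused vector
  z <- c(0.3, -0.2) %*% matrix(c(1, 0, 0, 1), 2) + c(0.1, 0)
  manual <- exp(z) / sum(exp(z))
  lg <- mpfusion:::softmax_rows(matrix(z, 1))
  expect_equal(as.numeric(lg), as.numeric(manual), tolerance = 1e-12)
})

naive_v <- function(head, ta, tb) {
  B <- dim(ta)[1]; d <- head$d
  V <- array(0, c(B, 3, d))
  for (b in seq_len(B)) {
    Tk <- rbind(ta[b, 1, ], tb[b, 1, ], head$par$cls)
    V[b, , ] <- Tk %*% head$par$v$weight
  }
  V
}

test_that("end-to-end forward matches the naive-loop oracle to 1e-5", {
  set.seed(3)
  head <- saff_head(d = 6, theta = 0.7, hidden = 5, seed = 9)
  ta <- array(rnorm(4 * 6), c(4, 1, 6))
  tb <- array(rnorm(4 * 6), c(4, 1, 6))
  fw <- saff_forward(head, ta, tb)
  ora <- naive_saff(head, ta, tb)
  expect_lt(max(abs(fw$probs - ora$probs)), 1e-5)
  expect_lt(max(abs(fw$g - ora$g)), 1e-5)
  expect_lt(max(abs(fw$f - ora$f)), 1e-5)
  expect_lt(max(abs(fw$h - ora$h)), 1e-5)
  expect_equal(fw$h, head$par$theta * naive_v(head, ta, tb) + fw$f,
               tolerance = 1e-10)
})

test_that("attention is equivariant under swapping the two modality tokens", {
  set.seed(4)
  head <- saff_head(d = 5, hidden = 4, seed = 11)
  ta <- array(rnorm(3 * 5), c(3, 1, 5))
  tb <- array(rnorm(3 * 5), c(3, 1, 5))
  fw <- saff_forward(head, ta, tb)
  sw <- saff_forward(head, tb, ta)
  perm <- c(2L, 1L, 3L)
  expect_equal(sw$g, fw$g[, perm, perm, drop = FALSE], tolerance = 1e-12)
  expect_equal(sw$f, fw$f[, perm, , drop = FALSE], tolerance = 1e-12)
  expect_equal(sw$h, fw$h[, perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("autodiff agrees with finite differences on theta and projections", {
  head <- saff_head(d = 4, theta = 0.6, theta_learnable = TRUE, hidden = 3,
                    seed = 12)
  set.seed(5)
  ta <- array(rnorm(2 * 4), c(2, 1, 4))
  tb <- array(rnorm(2 * 4), c(2, 1, 4))
  dy <- matrix(rnorm(4), 2, 2)
  fw <- saff_forward(head, ta, tb, keep_cache = TRUE)
  bw <- mpfusion:::saff_backward(head, fw$cache, dy)
  loss_with <- function(mutate) {
    h2 <- head
    h2$par <- mutate(h2$par)
    sum(saff_forward(h2, ta, tb)$logits * dy)
  }
  for (nm in c("q", "k", "v")) {
    p0 <- head$par[[nm]]$weight
    ng <- num_grad(function(pp) loss_with(function(par) {
      par[[nm]]$weight <- pp
      par
    }), p0, eps = 1e-6)
    expect_lt(max(abs(bw$grads[[nm]]$weight - ng)), 1e-4)
  }
  ng_theta <- num_grad(function(th) loss_with(function(par) {
    par$theta <- th
    par
  }), head$par$theta, eps = 1e-6)
  expect_lt(abs(bw$grads$theta - ng_theta), 1e-4)
  ng_tok <- num_grad(function(tt) sum(saff_forward(head, tt, tb)$logits * dy),
                     ta, eps = 1e-6)
  expect_lt(max(abs(bw$dtoken_a - ng_tok)), 1e-4)
})
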