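# Assembly of the full classification graphs. Every fusion strategy shares
# the same branch extractors, MA blocks and training interface; the mode
# decides how branch features reach the classifier:
#   saff           - tokens + class token through the self-attention head
#   single_a/b     - one modality, global pooling, two-FC classifier
#   input_level    - one shared branch over the pooled single-image dataset
#   feature_concat - branch tokens concatenated, two-FC classifier
#   feature_add    - branch tokens summed, two-FC classifier
# Decision-level fusion trains two single-modality models and combines
# their output distributions (see decision_level_fuse()).

two_fc <- function(din, hidden = 256L, seed = 1L) {
  set.seed(seed)
  list(fc1 = list(weight = init_dense(din, hidden), bias = numeric(hidden)),
       fc2 = list(weight = init_dense(hidden, 2L, sd = sqrt(1 / hidden)),
                  bias = numeric(2L)))
}

#' Build a paired-modality classification model
#'
#' @param arch Backbone architecture name (see [build_extractor()]).
#' @param mode Fusion strategy: `"saff"`, `"single_a"`, `"single_b"`,
#'   `"input_level"`, `"feature_concat"`, `"feature_add"`.
#' @param use_ma Attach a multiscale attention block to each branch.
#' @param theta,theta_learnable,readout SAFF head options (see
#'   [saff_head()]).
#' @param hidden Classifier hidden width.
#' @param pretrained,freeze Passed to [build_extractor()].
#' @param seed Master seed; branch/MA/head initialisations use derived
#'   seeds.
#' @return An object of class `smmf_model`.
#' @export
smmf_model <- function(arch = "compact_test",
                       mode = c("saff", "single_a", "single_b", "input_level",
                                "feature_concat", "feature_add"),
                       use_ma = TRUE, theta = 1, theta_learnable = FALSE,
                       readout = "full", hidden = 256L,
                       pretrained = FALSE, freeze = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  seed <- as.integer(seed)
  two_branch <- mode %in% c("saff", "feature_concat", "feature_add")
  branch_a <- build_extractor(arch, pretrained, seed = seed, freeze = freeze)
  branch_b <- if (two_branch) {
    build_extractor(arch, pretrained, seed = seed + 1L, freeze = freeze)
  } else NULL
  cdim <- branch_a$out_channels
  ma_a <- ma_b <- NULL
  if (use_ma) {
    # the compact configuration is norm-free end to end (see arch_compact_test)
    cfg <- ma_config(cdim, cdim %/% 2L, batchnorm = !identical(arch, "compact_test"))
    ma_a <- ma_block(cfg, seed = seed + 2L)
    if (two_branch) ma_b <- ma_block(cfg, seed = seed + 3L)
    cdim <- cdim %/% 2L
  }
  head <- classifier <- NULL
  if (mode == "saff") {
    head <- saff_head(d = cdim, theta = theta, theta_learnable = theta_learnable,
                      readout = readout, hidden = hidden, seed = seed + 4L)
  } else {
    din <- if (mode == "feature_concat") 2L * cdim else cdim
    classifier <- two_fc(din, hidden, seed = seed + 4L)
  }
  structure(list(arch = arch, mode = mode, use_ma = use_ma,
                 branch_a = branch_a, branch_b = branch_b,
                 ma_a = ma_a, ma_b = ma_b,
                 head = head, classifier = classifier,
                 token_dim = cdim, seed = seed),
            class = "smmf_model")
}

#' @export
print.smmf_model <- function(x, ...) {
  cat("<smmf_model> mode=", x$mode, " arch=", x$arch,
      " ma=", x$use_ma, " params=", model_param_count(x), "\n", sep = "")
  invisible(x)
}

#' Total trainable parameter count
#' @export
model_param_count <- function(model) {
  n <- extractor_param_count(model$branch_a)
  if (!is.null(model$branch_b)) n <- n + extractor_param_count(model$branch_b)
  if (!is.null(model$ma_a)) n <- n + ma_param_count(model$ma_a)
  if (!is.null(model$ma_b)) n <- n + ma_param_count(model$ma_b)
  if (!is.null(model$head)) n <- n + tree_count(model$head$par)
  if (!is.null(model$classifier)) n <- n + tree_count(model$classifier)
  n
}

# One branch forward: extractor (+ MA) + global pooling to a [B,1,d] token.
# Inputs in [0,1] are shifted to [-0.5, 0.5]: a constant offset (per-image
# standardisation would erase global-enhancement information) that keeps the
# first convolution's operating point centred.
branch_forward <- function(extractor, ma, x, training, branch) {
  ex <- extractor_forward(extractor, x - 0.5, training, branch = branch)
  fmap <- ex$out
  mac <- NULL
  if (!is.null(ma)) {
    mr <- ma_forward(ma, fmap, training, keep_cache = training)
    mac <- mr$cache
    ma <- mr$ma
    fmap <- mr$out
  }
  token <- pool_and_tokenize(fmap)
  list(token = token, extractor = ex$extractor, ma = ma,
       cache = list(backbone = ex$caches, ma = mac, fdim = dim(fmap)))
}

branch_backward <- function(extractor, ma, cache, dtoken) {
  fd <- cache$fdim
  dmap <- array(0, fd)
  hw <- fd[2] * fd[3]
  for (c in seq_len(fd[4])) dmap[, , , c] <- dtoken[, 1L, c] / hw
  g_ma <- NULL
  if (!is.null(ma)) {
    mb <- ma_backward(ma, cache$ma, dmap)
    g_ma <- mb$grads
    dmap <- mb$dx
  }
  g_bb <- NULL
  if (!extractor$freeze) {
    nb <- net_backward(extractor$net, cache$backbone, dmap)
    g_bb <- nb$grads
  }
  list(backbone = g_bb, ma = g_ma)
}

#' Forward pass of a model on an image batch pair
#'
#' @param model An [smmf_model()].
#' @param x1,x2 `[B, H, W, C]` arrays; single-modality and input-level modes
#'   use the relevant one.
#' @param training Keep caches and use batch statistics.
#' @return `list(model, probs, logits, caches)`; `probs` column 2 is the
#'   high-grade probability.
#' @export
model_forward <- function(model, x1, x2 = NULL, training = FALSE) {
  mode <- model$mode
  caches <- list()
  if (mode %in% c("single_a", "input_level")) {
    ba <- branch_forward(model$branch_a, model$ma_a, x1, training, "A")
    model$branch_a <- ba$extractor; model$ma_a <- ba$ma
    feat <- matrix(ba$token, dim(ba$token)[1], model$token_dim)
    caches$a <- ba$cache
  } else if (mode == "single_b") {
    if (is.null(x2)) stop("mode single_b needs x2")
    ba <- branch_forward(model$branch_a, model$ma_a, x2, training, "B")
    model$branch_a <- ba$extractor; model$ma_a <- ba$ma
    feat <- matrix(ba$token, dim(ba$token)[1], model$token_dim)
    caches$a <- ba$cache
  } else {
    if (is.null(x2)) stop("paired modes need both modalities")
    ba <- branch_forward(model$branch_a, model$ma_a, x1, training, "A")
    bb <- branch_forward(model$branch_b, model$ma_b, x2, training, "B")
    model$branch_a <- ba$extractor; model$ma_a <- ba$ma
    model$branch_b <- bb$extractor; model$ma_b <- bb$ma
    caches$a <- ba$cache; caches$b <- bb$cache
  }
  if (mode == "saff") {
    sf <- saff_forward(model$head, ba$token, bb$token, keep_cache = training)
    caches$saff <- sf$cache
    out <- list(probs = sf$probs, logits = sf$logits)
  } else {
    if (mode == "feature_concat") {
      feat <- feature_level_fuse(
        matrix(ba$token, dim(ba$token)[1], model$token_dim),
        matrix(bb$token, dim(bb$token)[1], model$token_dim), mode = "concat")
    } else if (mode == "feature_add") {
      feat <- feature_level_fuse(
        matrix(ba$token, dim(ba$token)[1], model$token_dim),
        matrix(bb$token, dim(bb$token)[1], model$token_dim), mode = "add")
    }
    z1 <- dense_forward(feat, model$classifier$fc1$weight, model$classifier$fc1$bias)
    a1 <- relu_forward(z1$out)
    z2 <- dense_forward(a1$out, model$classifier$fc2$weight, model$classifier$fc2$bias)
    caches$clf <- list(z1 = z1$cache, a1 = a1$cache, z2 = z2$cache)
    out <- list(probs = softmax_rows(z2$out), logits = z2$out)
  }
  list(model = model, probs = out$probs, logits = out$logits, caches = caches)
}

#' @noRd
model_backward <- function(model, caches, dlogits) {
  mode <- model$mode
  grads <- list()
  if (mode == "saff") {
    sb <- saff_backward(model$head, caches$saff, dlogits)
    grads$head <- sb$grads
    ga <- branch_backward(model$branch_a, model$ma_a, caches$a, sb$dtoken_a)
    gb <- branch_backward(model$branch_b, model$ma_b, caches$b, sb$dtoken_b)
    grads$branch_a <- ga; grads$branch_b <- gb
  } else {
    b2 <- dense_backward(dlogits, model$classifier$fc2$weight, caches$clf$z2)
    br <- relu_backward(b2$dx, caches$clf$a1)
    b1 <- dense_backward(br$dx, model$classifier$fc1$weight, caches$clf$z1)
    grads$classifier <- list(fc1 = list(weight = b1$dW, bias = b1$db),
                             fc2 = list(weight = b2$dW, bias = b2$db))
    dfeat <- b1$dx
    d <- model$token_dim
    B <- nrow(dfeat)
    if (mode %in% c("single_a", "single_b", "input_level")) {
      grads$branch_a <- branch_backward(model$branch_a, model$ma_a, caches$a,
                                        array(dfeat, c(B, 1L, d)))
    } else if (mode == "feature_concat") {
      da <- array(dfeat[, seq_len(d), drop = FALSE], c(B, 1L, d))
      db <- array(dfeat[, d + seq_len(d), drop = FALSE], c(B, 1L, d))
      grads$branch_a <- branch_backward(model$branch_a, model$ma_a, caches$a, da)
      grads$branch_b <- branch_backward(model$branch_b, model$ma_b, caches$b, db)
    } else {                      # feature_add
      dt <- array(dfeat, c(B, 1L, d))
      grads$branch_a <- branch_backward(model$branch_a, model$ma_a, caches$a, dt)
      grads$branch_b <- branch_backward(model$branch_b, model$ma_b, caches$b, dt)
    }
  }
  grads
}

# Optimiser state (momentum velocities) is carried in `state`, a list
# mirroring the model components; pass the returned state back in.
#' @noRd
model_update <- function(model, grads, lr, l1 = 0, momentum = 0, state = NULL) {
  if (is.null(state)) state <- list()
  if (!is.null(grads$branch_a$backbone) && !model$branch_a$freeze) {
    r <- net_update(model$branch_a$net, grads$branch_a$backbone, lr, l1,
                    momentum, state$a)
    model$branch_a$net <- r$net
    state$a <- r$vel
  }
  if (!is.null(grads$branch_a$ma)) {
    r <- tree_sgd(model$ma_a$par, grads$branch_a$ma, lr, l1, momentum, state$ma_a)
    model$ma_a$par <- r$par
    state$ma_a <- r$vel
  }
  if (!is.null(model$branch_b) && !is.null(grads$branch_b$backbone) &&
      !model$branch_b$freeze) {
    r <- net_update(model$branch_b$net, grads$branch_b$backbone, lr, l1,
                    momentum, state$b)
    model$branch_b$net <- r$net
    state$b <- r$vel
  }
  if (!is.null(model$ma_b) && !is.null(grads$branch_b$ma)) {
    r <- tree_sgd(model$ma_b$par, grads$branch_b$ma, lr, l1, momentum, state$ma_b)
    model$ma_b$par <- r$par
    state$ma_b <- r$vel
  }
  if (!is.null(grads$head)) {
    r <- tree_sgd(model$head$par, grads$head, lr, l1, momentum, state$head)
    model$head$par <- r$par
    state$head <- r$vel
  }
  if (!is.null(grads$classifier)) {
    r <- tree_sgd(model$classifier, grads$classifier, lr, l1, momentum, state$clf)
    model$classifier <- r$par
    state$clf <- r$vel
  }
  list(model = model, state = state)
}

#' @noRd
model_l1 <- function(model) {
  s <- net_l1(model$branch_a$net)
  if (!is.null(model$branch_b)) s <- s + net_l1(model$branch_b$net)
  if (!is.null(model$ma_a)) s <- s + tree_l1(model$ma_a$par)
  if (!is.null(model$ma_b)) s <- s + tree_l1(model$ma_b$par)
  if (!is.null(model$head)) s <- s + tree_l1(model$head$par)
  if (!is.null(model$classifier)) s <- s + tree_l1(model$classifier)
  s
}

# Snapshot/restore of all trainable parameters (early stopping).
model_snapshot <- function(model) {
  list(a = lapply(model$branch_a$net, `[[`, "par"),
       b = if (!is.null(model$branch_b)) lapply(model$branch_b$net, `[[`, "par"),
       ma_a = if (!is.null(model$ma_a)) model$ma_a$par,
       ma_b = if (!is.null(model$ma_b)) model$ma_b$par,
       head = if (!is.null(model$head)) model$head$par,
       clf = model$classifier)
}

model_restore <- function(model, snap) {
  for (i in seq_along(snap$a)) model$branch_a$net[[i]]$par <- snap$a[[i]]
  if (!is.null(snap$b)) {
    for (i in seq_along(snap$b)) model$branch_b$net[[i]]$par <- snap$b[[i]]
  }
  if (!is.null(snap$ma_a)) model$ma_a$par <- snap$ma_a
  if (!is.null(snap$ma_b)) model$ma_b$par <- snap$ma_b
  if (!is.null(snap$head)) model$head$par <- snap$head
  if (!is.null(snap$clf)) model$classifier <- snap$clf
  model
}
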