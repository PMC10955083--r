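#' Build a per-modality feature extractor
#'
#' Constructs one branch of the dual-branch feature extraction stage: a
#' convolutional network truncated before any classification head, mapping a
#' `[B, H, W, 3]` image batch to a `[B, h, w, c]` feature map. The default
#' dense-connectivity architecture maps 224 x 224 inputs to `[B, 7, 7, 1024]`
#' (stride product 32); the compact test backbone maps 32 x 32 inputs to
#' `[B, 1, 1, 64]` so the full fusion graph trains in seconds on a CPU.
#'
#' Available architectures:
#' * `"densenet121"` (default): dense-connectivity network, blocks of
#'   6/12/24/16 bottlenecked dense units, growth rate 32; output 1024
#'   channels at 1/32 resolution.
#' * `"resnet50"`: residual bottleneck network, stages 3/4/6/3; output 2048
#'   channels at 1/32 resolution.
#' * `"xception_like"`: depthwise-separable convolution stack; output 1024
#'   channels at 1/32 resolution.
#' * `"compact_test"`: three conv/pool stages, 64 output channels, for fast
#'   CPU experiments and tests.
#'
#' @param arch_name One of `"densenet121"`, `"resnet50"`, `"xception_like"`,
#'   `"compact_test"`.
#' @param pretrained Either `FALSE` (random initialisation from `seed`) or a
#'   path to an `.rds` file holding a parameter list previously saved with
#'   [extractor_save_weights()]. Weights are never downloaded.
#' @param seed Integer seed for the random initialisation.
#' @param freeze If `TRUE` the extractor's parameters are not updated during
#'   training.
#' @return An object of class `mp_extractor`.
#' @examples
#' ex <- build_extractor("compact_test", seed = 1)
#' x <- array(0.5, c(2, 32, 32, 3))
#' dim(extractor_forward(ex, x)$out)  # 2 1 1 64
#' @export
build_extractor <- function(arch_name = c("densenet121", "resnet50",
                                          "xception_like", "compact_test"),
                            pretrained = FALSE, seed = 1L, freeze = FALSE) {
  arch_name <- match.arg(arch_name)
  if (!isFALSE(pretrained) && arch_name == "compact_test") {
    stop("pretrained weights are not defined for the compact test backbone")
  }
  set.seed(seed)
  net <- switch(arch_name,
    densenet121 = arch_densenet121(),
    resnet50 = arch_resnet50(),
    xception_like = arch_xception_like(),
    compact_test = arch_compact_test()
  )
  out_channels <- switch(arch_name,
    densenet121 = 1024L, resnet50 = 2048L, xception_like = 1024L,
    compact_test = 64L)
  ex <- structure(
    list(arch = arch_name, net = net, out_channels = out_channels,
         stride_product = 32L, freeze = isTRUE(freeze), seed = as.integer(seed)),
    class = "mp_extractor")
  if (!isFALSE(pretrained)) ex <- extractor_load_weights(ex, pretrained)
  ex
}

arch_densenet121 <- function(growth = 32L) {
  net <- list(
    layer_conv(7, 7, 3, 64, stride = 2),
    layer_bn(64), layer_relu(),
    layer_maxpool(3, 2, padding = 1)
  )
  cin <- 64L
  blocks <- c(6L, 12L, 24L, 16L)
  for (bi in seq_along(blocks)) {
    for (u in seq_len(blocks[bi])) {
      net <- c(net, list(layer_dense_unit(cin, growth)))
      cin <- cin + growth
    }
    if (bi < length(blocks)) {
      cout <- cin %/% 2L
      net <- c(net, list(layer_bn(cin), layer_relu(),
                         layer_conv(1, 1, cin, cout),
                         layer_avgpool(2)))
      cin <- cout
    }
  }
  c(net, list(layer_bn(cin), layer_relu()))
}

arch_resnet50 <- function() {
  net <- list(
    layer_conv(7, 7, 3, 64, stride = 2),
    layer_bn(64), layer_relu(),
    layer_maxpool(3, 2, padding = 1)
  )
  widths <- c(64L, 128L, 256L, 512L)
  reps <- c(3L, 4L, 6L, 3L)
  cin <- 64L
  for (s in seq_along(widths)) {
    for (r in seq_len(reps[s])) {
      stride <- if (r == 1L && s > 1L) 2L else 1L
      net <- c(net, list(layer_bottleneck(cin, widths[s], stride)))
      cin <- 4L * widths[s]
    }
  }
  net
}

arch_xception_like <- function() {
  list(
    layer_conv(3, 3, 3, 32, stride = 2), layer_bn(32), layer_relu(),
    layer_conv(3, 3, 32, 64), layer_bn(64), layer_relu(),
    layer_sepconv(64, 128), layer_bn(128), layer_relu(), layer_maxpool(3, 2, 1),
    layer_sepconv(128, 256), layer_bn(256), layer_relu(), layer_maxpool(3, 2, 1),
    layer_sepconv(256, 512), layer_bn(512), layer_relu(), layer_maxpool(3, 2, 1),
    layer_sepconv(512, 1024), layer_bn(1024), layer_relu(), layer_maxpool(3, 2, 1)
  )
}

# Average pooling (not max): the synthetic-benchmark cues are weak
# distributed patterns, and averaging rectified filter responses is the
# convolutional analogue of matched filtering. Norm-free: with batch size 8
# and cohorts of ~10^2 slices, batchnorm's train/eval statistics mismatch
# dominates weak signals, so the compact configuration uses plain
# convolutions (the large backbones keep batchnorm).
arch_compact_test <- function() {
  list(
    layer_conv(3, 3, 3, 16), layer_relu(), layer_avgpool(4),
    layer_conv(3, 3, 16, 32), layer_relu(), layer_avgpool(4),
    layer_conv(3, 3, 32, 64), layer_relu(), layer_avgpool(2)
  )
}

#' Run a feature extractor forward
#'
#' @param extractor An `mp_extractor` from [build_extractor()].
#' @param x Image batch array `[B, H, W, C]` with pixel values in `[0, 1]`.
#' @param training Use batch statistics and keep backward caches.
#' @return `list(out, caches, extractor)`; `out` is the `[B, h, w, c]`
#'   feature map with `branch`/`stage` provenance attributes.
#' @export
extractor_forward <- function(extractor, x, training = FALSE, branch = NA_character_) {
  stopifnot(inherits(extractor, "mp_extractor"))
  if (length(dim(x)) != 4L) stop("expected a [B, H, W, C] array")
  r <- net_forward(extractor$net, x, training = training,
                   keep_cache = training && !extractor$freeze)
  extractor$net <- r$net
  out <- r$out
  attr(out, "branch") <- branch
  attr(out, "stage") <- "backbone"
  list(out = out, caches = r$caches, extractor = extractor)
}

#' Extract features for a paired-modality batch
#'
#' Runs modality A and modality B through their own, independently
#' parameterised branch networks (no weight sharing).
#'
#' @param x1,x2 Image batch arrays `[B, H, W, C]` for modality A and B.
#' @param extractor_a,extractor_b The two branch extractors.
#' @return A list with feature maps `a` and `b`.
#' @export
extract_pair <- function(x1, x2, extractor_a, extractor_b, training = FALSE) {
  if (!identical(dim(x1), dim(x2))) {
    stop("modality batches disagree in shape: [", paste(dim(x1), collapse = ","),
         "] vs [", paste(dim(x2), collapse = ","), "]")
  }
  ra <- extractor_forward(extractor_a, x1, training, branch = "A")
  rb <- extractor_forward(extractor_b, x2, training, branch = "B")
  list(a = ra$out, b = rb$out,
       caches_a = ra$caches, caches_b = rb$caches,
       extractor_a = ra$extractor, extractor_b = rb$extractor)
}

#' Number of trainable parameters of an extractor
#' @export
extractor_param_count <- function(extractor) net_param_count(extractor$net)

#' Save / load extractor weights
#'
#' Weights are stored as a plain parameter list in an `.rds` file; this is
#' the mechanism for supplying transfer-learning initialisations from the
#' user's own ecosystem.
#' @export
extractor_save_weights <- function(extractor, path) {
  saveRDS(lapply(extractor$net, `[[`, "par"), path)
  invisible(path)
}

#' @rdname extractor_save_weights
#' @export
extractor_load_weights <- function(extractor, path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  pars <- readRDS(path)
  if (length(pars) != length(extractor$net)) {
    stop("weights file does not match architecture ", extractor$arch)
  }
  for (i in seq_along(pars)) extractor$net[[i]]$par <- pars[[i]]
  extractor
}
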