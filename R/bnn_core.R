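# Floating-point reference implementation of the binarized network forward
# pass. Weights and activations live in {0,1}; multiplication is logical AND
# and dot products are popcounts. Batch norm runs in real arithmetic here;
# the integer-only twin lives in hw_fold.R.

#' 0,1 binarization
#'
#' Maps a value to 1 if it is strictly positive and to 0 otherwise,
#' elementwise. This is the activation and weight binarization used
#' throughout the network; it is idempotent.
#'
#' @param x Numeric vector, matrix or array.
#' @return Integer object of the same shape with entries in `{0,1}`.
#' @examples
#' binarize(c(-2, 0, 0.5))  # 0 0 1
#' @export
binarize <- function(x) {
  out <- x
  out[] <- as.integer(x > 0)
  if (is.matrix(x) || is.array(x)) out else as.integer(out)
}

#' Valid binary convolution (popcount)
#'
#' Convolves a 0/1 image with a 0/1 kernel, "valid" padding: each output is
#' the count of positions where image and kernel are both 1 (logical AND
#' plus popcount, the binary-network dot product).
#'
#' @param image 0/1 matrix.
#' @param kernel 0/1 `KO` x `KO` matrix, no larger than the image.
#' @param stride Convolution stride.
#' @return Integer matrix of popcounts, side `(side - KO)/stride + 1`.
#' @export
bconv_valid <- function(image, kernel, stride = 1L) {
  assert_binary(image); assert_binary(kernel)
  if (nrow(kernel) > nrow(image)) stop("kernel larger than image")
  idx <- conv_indices(nrow(image), nrow(kernel), stride)
  out <- conv_batch(as_image_row(image), as.integer(kernel), idx)
  row_to_image(out, attr(idx, "out_side"))
}

#' OR max-pooling of a binary grid
#'
#' Max-pooling over 0/1 values reduces to a logical OR of each pooling
#' window.
#'
#' @param bits 0/1 matrix.
#' @param P Pooling window side.
#' @param SP Pooling stride.
#' @return 0/1 integer matrix of side `(side - P)/SP + 1`.
#' @export
or_maxpool <- function(bits, P = 2L, SP = 2L) {
  assert_binary(bits)
  if (nrow(bits) < P) stop("grid smaller than pooling window")
  idx <- conv_indices(nrow(bits), P, SP)
  out <- pool_batch(as_image_row(bits), idx)
  row_to_image(out, attr(idx, "out_side"))
}

.bn_apply <- function(x, gamma, beta, mu, sigma, eps) {
  gamma * (x - mu) / sqrt(sigma^2 + eps) + beta
}

#' Depthwise-separable convolution forward pass
#'
#' Per input channel, a depthwise `KD` x `KD` binary convolution produces an
#' integer popcount grid (held as small integers, not binarized); per output
#' channel, a pointwise 1x1 binary kernel sums the depthwise grids of the
#' channels it selects, after which batch norm and 0,1 binarization are
#' applied. Equivalent to a conventional 3D convolution whose kernels are
#' the rank-1 products of the depthwise and pointwise factors.
#'
#' @param maps `side` x `side` x `K` 0/1 array of input feature maps.
#' @param dw `KD^2` x `K` 0/1 matrix of depthwise kernels (column-major
#'   cells).
#' @param pw `K` x `KP` 0/1 matrix of pointwise kernels.
#' @param bn Data frame with columns `gamma`, `beta`, `mu`, `sigma` (one row
#'   per output channel).
#' @param eps Batch-norm stabilizer.
#' @return List with `out` (`MD` x `MD` x `KP` 0/1 array), `presums` (the
#'   integer pointwise sums before batch norm) and `dw_maps` (the integer
#'   depthwise grids).
#' @export
dsc_forward <- function(maps, dw, pw, bn, eps = 1e-4) {
  stopifnot(length(dim(maps)) == 3L)
  K <- dim(maps)[3]
  if (ncol(dw) != K || nrow(pw) != K) stop("mismatched channel counts")
  KP <- ncol(pw)
  if (nrow(bn) != KP) stop("mismatched channel counts")
  side <- dim(maps)[1]
  kd <- as.integer(sqrt(nrow(dw)))
  if (side < kd) stop("map side smaller than depthwise kernel")
  idx <- conv_indices(side, kd, 1L)
  md <- attr(idx, "out_side")
  dwm <- array(0L, c(md, md, K))
  for (ch in seq_len(K)) {
    dwm[, , ch] <- row_to_image(
      conv_batch(as_image_row(maps[, , ch]), dw[, ch], idx), md)
  }
  presums <- array(0L, c(md, md, KP))
  out <- array(0L, c(md, md, KP))
  for (p in seq_len(KP)) {
    s <- matrix(0L, md, md)
    for (ch in which(pw[, p] != 0)) s <- s + dwm[, , ch]
    presums[, , p] <- s
    out[, , p] <- binarize(.bn_apply(s, bn$gamma[p], bn$beta[p], bn$mu[p],
                                     bn$sigma[p], eps))
  }
  list(out = out, presums = presums, dw_maps = dwm)
}

# ---- weights -------------------------------------------------------------

.new_weights <- function(cfg, conv1, dw, pw, bn_dsc, fc1, bn_fc1, fc2,
                         bn_fc2, log = NULL) {
  structure(list(cfg = cfg, conv1 = conv1, dw = dw, pw = pw, bn_dsc = bn_dsc,
                 fc1 = fc1, bn_fc1 = bn_fc1, fc2 = fc2, bn_fc2 = bn_fc2,
                 log = log),
            class = "bdscnn_weights")
}

#' @export
print.bdscnn_weights <- function(x, ...) {
  cat(sprintf("bdscnn_weights: conv1 %dx%d, dw %dx%d, pw %dx%d, fc1 %dx%d, fc2 %dx%d\n",
              nrow(x$conv1), ncol(x$conv1), nrow(x$dw), ncol(x$dw),
              nrow(x$pw), ncol(x$pw), nrow(x$fc1), ncol(x$fc1),
              nrow(x$fc2), ncol(x$fc2)))
  invisible(x)
}

.random_bn <- function(n, mu_range, sigma_range, neg_gamma_prob = 0.1) {
  data.frame(
    gamma = stats::runif(n, 0.5, 1.5) *
      ifelse(stats::runif(n) < neg_gamma_prob, -1, 1),
    beta = stats::rnorm(n),
    mu = stats::runif(n, mu_range[1], mu_range[2]),
    sigma = stats::runif(n, sigma_range[1], sigma_range[2]))
}

#' Draw a random weight set
#'
#' Random binary masks (independent Bernoulli(1/2) bits) and batch-norm
#' parameters in the ranges a trained model of this architecture occupies.
#' Used by the equivalence and folding property tests; not a trained model.
#'
#' @param cfg A `bdscnn_config`.
#' @param rng_seed Integer seed.
#' @return A `bdscnn_weights` object.
#' @export
random_weights <- function(cfg = bdscnn_config(), rng_seed = 1L) {
  with_seed(rng_seed, {
    rbits <- function(nr, nc) matrix(as.integer(stats::runif(nr * nc) < 0.5),
                                     nr, nc)
    .new_weights(
      cfg,
      conv1 = rbits(cfg$KO^2, cfg$K),
      dw = rbits(cfg$KD^2, cfg$K),
      pw = rbits(cfg$K, cfg$KP),
      bn_dsc = .random_bn(cfg$KP, c(2, 14), c(1, 5)),
      fc1 = rbits(cfg$fc1_inputs, cfg$F1),
      bn_fc1 = .random_bn(cfg$F1, c(200, 1100), c(20, 200)),
      fc2 = rbits(cfg$F1, cfg$C),
      bn_fc2 = .random_bn(cfg$C, c(4, 28), c(1, 6)))
  })
}

# ---- batched reference forward ------------------------------------------

.geometry_indices <- function(cfg) {
  ic <- conv_indices(cfg$M, cfg$KO, cfg$SO)
  ip <- conv_indices(cfg$conv_side, cfg$P, cfg$SP)
  id <- conv_indices(cfg$pool_side, cfg$KD, 1L)
  list(conv = ic, pool = ip, dw = id)
}

# X: n x M^2 0/1, RR: n x rr_bits. Returns the full stack of intermediates.
.forward_ref_batch <- function(X, RR, w, idx = .geometry_indices(w$cfg)) {
  cfg <- w$cfg
  n <- nrow(X)
  Z <- matrix(0L, n, cfg$dsc_side^2 * cfg$KP)
  dwm <- vector("list", cfg$K)
  for (ch in seq_len(cfg$K)) {
    a1 <- conv_batch(X, w$conv1[, ch], idx$conv)
    h1 <- (a1 > 0) * 1L
    pooled <- pool_batch(h1, idx$pool)
    dwm[[ch]] <- conv_batch(pooled, w$dw[, ch], idx$dw)
  }
  npos <- cfg$dsc_side^2
  for (p in seq_len(cfg$KP)) {
    s <- matrix(0L, n, npos)
    for (ch in which(w$pw[, p] != 0)) s <- s + dwm[[ch]]
    y <- .bn_apply(s, w$bn_dsc$gamma[p], w$bn_dsc$beta[p], w$bn_dsc$mu[p],
                   w$bn_dsc$sigma[p], cfg$eps)
    Z[, (p - 1L) * npos + seq_len(npos)] <- (y > 0) * 1L
  }
  Zfull <- cbind(Z, RR)
  fc1_pre <- Zfull %*% w$fc1
  h4 <- (.bn_apply_cols(fc1_pre, w$bn_fc1, cfg$eps) > 0) * 1L
  fc2_pre <- h4 %*% w$fc2
  fc2_bn <- .bn_apply_cols(fc2_pre, w$bn_fc2, cfg$eps)
  sm <- exp(fc2_bn - apply(fc2_bn, 1, max))
  sm <- sm / rowSums(sm)
  list(fc1_pre = fc1_pre, fc1_bits = h4, fc2_pre = fc2_pre, fc2_bn = fc2_bn,
       scores = sm, pred = max.col(fc2_bn, ties.method = "first"))
}

# columnwise batch norm with stored parameters (one bn row per column)
.bn_apply_cols <- function(Xmat, bn, eps) {
  xc <- sweep(Xmat, 2, bn$mu)
  xc <- sweep(xc, 2, sqrt(bn$sigma^2 + eps), "/")
  sweep(sweep(xc, 2, bn$gamma, "*"), 2, bn$beta, "+")
}

#' Reference forward pass of the binarized network
#'
#' Runs the full floating-point reference pipeline on one image:
#' first-layer binary convolution, 0,1 binarization at threshold 0,
#' OR-max-pooling, depthwise-separable convolution with batch norm, then the
#' two fully connected layers (popcount, batch norm, binarize for FC1;
#' popcount, batch norm, softmax for FC2). The deployment classification is
#' the argmax of the FC2 batch-norm outputs (softmax is monotone and exists
#' for training); ties break toward the earliest class (N before S before V
#' before F before Q).
#'
#' @param image `M` x `M` 0/1 matrix.
#' @param rr_code Length-`rr_bits` 0/1 vector (RR interval code).
#' @param w A `bdscnn_weights` object.
#' @return List with `scores` (softmax probabilities, named by class),
#'   `label` (predicted class), `fc2_bn` (pre-softmax outputs) and `fc1_pre`
#'   (integer FC1 pre-activations, the quantity blockwise inference
#'   accumulates).
#' @export
forward <- function(image, rr_code, w) {
  stopifnot(inherits(w, "bdscnn_weights"))
  cfg <- w$cfg
  if (!is.matrix(image) || nrow(image) != cfg$M || ncol(image) != cfg$M) {
    stop("image must be ", cfg$M, "x", cfg$M)
  }
  assert_binary(image)
  if (length(rr_code) != cfg$rr_bits) stop("rr_code must have ", cfg$rr_bits,
                                           " bits")
  assert_binary(rr_code)
  res <- .forward_ref_batch(as_image_row(image),
                            matrix(as.integer(rr_code), nrow = 1L), w)
  cls <- beat_classes()[seq_len(cfg$C)]
  v <- res$fc2_bn[1L, ]
  list(scores = stats::setNames(res$scores[1L, ], cls),
       label = cls[which.max(v)],
       fc2_bn = stats::setNames(v, cls),
       fc1_pre = as.integer(res$fc1_pre[1L, ]))
}

# ---- cost accounting -----------------------------------------------------

#' Parameter and operation counts of the second (separable) layer
#'
#' Closed-form accounting of the network's kernel inventory and of the
#' convolutional operation count `C_operation` of the second layer, for
#' either the depthwise-separable layer or a conventional (non-separable)
#' convolution of identical geometry. Per channel, a conventional layer
#' needs `KD^2 * KP` weights against `KD^2 + KP` for the separable
#' factorization -- a 6x reduction at `KP = 18`.
#'
#' @param cfg A `bdscnn_config`.
#' @param second_layer `"dsc"` or `"conventional"`.
#' @return List with `kernel_count`, `kernel_params_total`,
#'   `second_layer_params`, `coperation`, `per_channel_conventional`,
#'   `per_channel_dsc` and `dsc_param_reduction`.
#' @examples
#' count_params_and_ops(bdscnn_config(), "dsc")$coperation        # 13689
#' count_params_and_ops(bdscnn_config(), "conventional")$coperation # 82134
#' @export
count_params_and_ops <- function(cfg = bdscnn_config(),
                                 second_layer = c("dsc", "conventional")) {
  second_layer <- match.arg(second_layer)
  md2 <- cfg$dsc_side^2
  if (second_layer == "dsc") {
    params2 <- cfg$KD^2 * cfg$K + cfg$K * cfg$KP
    cop <- md2 * cfg$K * cfg$KD^2 + md2 * cfg$KP * cfg$K
    kernels <- cfg$K + cfg$K + cfg$KP
  } else {
    params2 <- cfg$KD^2 * cfg$K * cfg$KP
    cop <- md2 * cfg$KP * cfg$KD^2 * cfg$K
    kernels <- cfg$K + cfg$KP
  }
  list(kernel_count = as.integer(kernels),
       kernel_params_total = as.integer(cfg$K * cfg$KO^2 + params2),
       second_layer_params = as.integer(params2),
       coperation = as.integer(cop),
       per_channel_conventional = as.integer(cfg$KD^2 * cfg$KP),
       per_channel_dsc = as.integer(cfg$KD^2 + cfg$KP),
       dsc_param_reduction = (cfg$KD^2 * cfg$KP) / (cfg$KD^2 + cfg$KP))
}
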