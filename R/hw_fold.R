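# Batch-norm folding and the integer-only inference twin.
#
# For an integer pre-activation s and batch-norm parameters with gamma > 0,
#   gamma*(s - mu)/sqrt(sigma^2 + eps) + beta > 0  <=>  s > t,
#   t = mu - beta*sqrt(sigma^2 + eps)/gamma,
# and since s is an integer, s > t <=> s > floor(t): the whole BN-plus-
# binarize stage collapses into one integer comparison. For gamma < 0 the
# inequality direction flips (s < t <=> s < ceiling(t)). The FC2 batch norm
# is not followed by a binarization, so it becomes a lookup table over the
# few attainable popcount sums instead.

#' Real-valued batch-norm comparator bound
#'
#' The pre-floor threshold `mu - beta*sqrt(sigma^2 + eps)/gamma` at which a
#' batch-normalized pre-activation crosses zero.
#'
#' @param p List or one-row data frame with `gamma`, `beta`, `mu`, `sigma`.
#' @param eps Batch-norm stabilizer.
#' @return Double.
#' @export
bn_threshold_value <- function(p, eps = 1e-4) {
  if (p$gamma == 0) stop("gamma = 0: batch norm cannot be folded")
  if (p$sigma^2 + eps <= 0) stop("sigma^2 + eps must be positive")
  p$mu - p$beta * sqrt(p$sigma^2 + eps) / p$gamma
}

#' Fold a batch-norm + binarize stage into an integer threshold
#'
#' Returns the integer comparator threshold: for `gamma > 0` the folded
#' activation fires (outputs 1) iff the integer pre-activation is strictly
#' greater than `floor` of the real bound; for `gamma < 0` the comparison
#' direction flips (fires iff the pre-activation is strictly less than the
#' `ceiling` of the bound) and the result is flagged via the `flipped`
#' attribute.
#'
#' @inheritParams bn_threshold_value
#' @return Integer threshold with attributes `pre_floor` (the real bound)
#'   and `flipped` (logical).
#' @examples
#' p <- list(gamma = 0.7093, beta = -2.0248, mu = 0.8035, sigma = 0.9242)
#' fold_bn_threshold(p)  # 3, pre-floor approximately 3.4419
#' @export
fold_bn_threshold <- function(p, eps = 1e-4) {
  t <- bn_threshold_value(p, eps)
  flipped <- p$gamma < 0
  thr <- if (flipped) as.integer(ceiling(t)) else as.integer(floor(t))
  structure(thr, pre_floor = t, flipped = flipped)
}

.fold_bn_vec <- function(bn, eps) {
  n <- nrow(bn)
  thr <- integer(n)
  flip <- logical(n)
  pre <- numeric(n)
  for (i in seq_len(n)) {
    f <- fold_bn_threshold(bn[i, ], eps)
    thr[i] <- f
    flip[i] <- attr(f, "flipped")
    pre[i] <- attr(f, "pre_floor")
  }
  list(threshold = thr, flipped = flip, pre_floor = pre)
}

# compare integer sums against folded thresholds, flip-aware; S is n x units
.fold_fire <- function(S, fold) {
  out <- sweep(S, 2, fold$threshold, ">")
  if (any(fold$flipped)) {
    fl <- which(fold$flipped)
    out[, fl] <- sweep(S[, fl, drop = FALSE], 2, fold$threshold[fl], "<")
  }
  out * 1L
}

#' Build the FC2 batch-norm lookup table
#'
#' The FC2 popcount can only take the integers `0..max_sum`, so its batch
#' norm reduces to a precomputed table. Entries are the batch-norm outputs
#' quantized to 13-bit signed fixed point with 6 fractional bits (step
#' 1/64); values outside the representable range are an error.
#'
#' @param p List or one-row data frame with `gamma`, `beta`, `mu`, `sigma`.
#' @param max_sum Largest attainable popcount (>= 1).
#' @param frac_bits Fractional bits of the fixed-point representation.
#' @param total_bits Total signed width.
#' @param eps Batch-norm stabilizer.
#' @return Integer vector of `max_sum + 1` fixed-point codes (value * 64),
#'   with attribute `exact` holding the unquantized batch-norm outputs.
#' @export
build_fc2_lut <- function(p, max_sum, frac_bits = 6L, total_bits = 13L,
                          eps = 1e-4) {
  if (max_sum < 1L) stop("max_sum must be >= 1")
  s <- 0:max_sum
  exact <- p$gamma * (s - p$mu) / sqrt(p$sigma^2 + eps) + p$beta
  q <- as.integer(round(exact * 2^frac_bits))
  lim <- 2^(total_bits - 1L)
  if (any(q < -lim | q > lim - 1L)) {
    bad <- which(q < -lim | q > lim - 1L)[1L]
    stop(sprintf("LUT entry for sum %d (%.4f) overflows %d-bit fixed point",
                 s[bad], exact[bad], total_bits))
  }
  structure(q, exact = exact)
}

#' Fold a trained model for integer-only inference
#'
#' Converts reference weights into their deployment form: the first-layer
#' kernels become merged convolution-pooling kernels (valid because the
#' first-layer activation threshold is exactly 0), every batch-norm +
#' binarize stage becomes an integer comparator threshold
#' (see [fold_bn_threshold()]), and the FC2 batch norm becomes one lookup
#' table per class over its attainable popcounts (see [build_fc2_lut()]).
#' Classification by the folded model agrees with the reference model's
#' argmax on every input.
#'
#' @param w A `bdscnn_weights` object.
#' @return An object of class `bdscnn_folded`.
#' @export
fold_model <- function(w) {
  stopifnot(inherits(w, "bdscnn_weights"))
  cfg <- w$cfg
  mcpks <- lapply(seq_len(cfg$K), function(ch) {
    build_mcpk(matrix(w$conv1[, ch], cfg$KO, cfg$KO), cfg$SO, cfg$P, cfg$SP)
  })
  luts <- lapply(seq_len(cfg$C), function(cl) {
    build_fc2_lut(w$bn_fc2[cl, ], max_sum = max(1L, sum(w$fc2[, cl])),
                  eps = cfg$eps)
  })
  structure(list(cfg = cfg, mcpks = mcpks, dw = w$dw, pw = w$pw,
                 pw_fold = .fold_bn_vec(w$bn_dsc, cfg$eps),
                 fc1 = w$fc1, fc1_fold = .fold_bn_vec(w$bn_fc1, cfg$eps),
                 fc2 = w$fc2,
                 fc2_lut = lapply(luts, as.integer),
                 fc2_lut_exact = lapply(luts, attr, "exact")),
            class = "bdscnn_folded")
}

#' @export
print.bdscnn_folded <- function(x, ...) {
  cat(sprintf("bdscnn_folded: %d MCP kernels (%s nonzero), %d PW + %d FC1 thresholds, %d LUTs\n",
              length(x$mcpks),
              paste(vapply(x$mcpks, function(k) k$nonzero_count, integer(1)),
                    collapse = "+"),
              length(x$pw_fold$threshold), length(x$fc1_fold$threshold),
              length(x$fc2_lut)))
  invisible(x)
}

.check_width <- function(x, bits, signed, what) {
  lim <- if (signed) c(-2^(bits - 1), 2^(bits - 1) - 1) else c(0, 2^bits - 1)
  if (any(x < lim[1] | x > lim[2])) {
    warning(sprintf("%s exceeds declared %d-bit range [%d, %d]", what, bits,
                    lim[1], lim[2]), call. = FALSE)
  }
  invisible(x)
}

# Batched integer-only inference. X: n x M^2, RR: n x rr_bits.
.integer_forward_batch <- function(X, RR, fm, strict = FALSE) {
  cfg <- fm$cfg
  n <- nrow(X)
  KR <- nrow(fm$mcpks[[1L]]$bits)
  idx_m <- conv_indices(cfg$M, KR, fm$mcpks[[1L]]$stride)
  idx_d <- conv_indices(cfg$pool_side, cfg$KD, 1L)
  npos <- cfg$dsc_side^2
  dwm <- vector("list", cfg$K)
  for (ch in seq_len(cfg$K)) {
    m <- .mcp_apply_batch(X, fm$mcpks[[ch]], idx_m)
    dwm[[ch]] <- conv_batch(m, fm$dw[, ch], idx_d)
    if (strict) .check_width(dwm[[ch]], 4L, FALSE, "DW popcount")
  }
  Z <- matrix(0L, n, npos * cfg$KP)
  for (p in seq_len(cfg$KP)) {
    s <- matrix(0L, n, npos)
    for (ch in which(fm$pw[, p] != 0)) s <- s + dwm[[ch]]
    fire <- if (fm$pw_fold$flipped[p]) s < fm$pw_fold$threshold[p]
            else s > fm$pw_fold$threshold[p]
    Z[, (p - 1L) * npos + seq_len(npos)] <- fire * 1L
  }
  fc1_pre <- cbind(Z, RR) %*% fm$fc1
  if (strict) .check_width(fc1_pre, 12L, FALSE, "FC1 accumulator")
  h <- .fold_fire(fc1_pre, fm$fc1_fold)
  s2 <- h %*% fm$fc2
  if (strict) .check_width(s2, 5L, FALSE, "FC2 popcount")
  vals <- matrix(0, n, cfg$C)
  for (cl in seq_len(cfg$C)) {
    vals[, cl] <- fm$fc2_lut_exact[[cl]][s2[, cl] + 1L]
  }
  pred <- max.col(vals, ties.method = "first")
  list(pred = pred, lut_values = vals, fc2_sums = s2, fc1_pre = fc1_pre)
}

#' Integer-only forward pass (hardware twin)
#'
#' Classifies one image using only the operations the deployed datapath
#' has: AND/popcount convolutions with the merged kernels, integer
#' accumulation, integer threshold comparisons, and a lookup into the
#' precomputed FC2 batch-norm table, whose stored entries are compared to
#' pick the class (ties to the earliest class). In strict mode the
#' intermediate values are additionally checked against the hardware
#' register widths (4-bit depthwise popcounts, 12-bit FC1 accumulators,
#' 5-bit FC2 popcounts), with a warning on overflow; strict and default
#' modes always classify identically.
#'
#' @param image `M` x `M` 0/1 matrix.
#' @param rr_code Length-`rr_bits` 0/1 vector.
#' @param fm A `bdscnn_folded` model.
#' @param strict Check declared hardware register widths.
#' @return List with `onehot` (named 0/1 vector with exactly one 1),
#'   `label`, `lut_values` (the looked-up per-class scores) and `fc2_sums`.
#' @export
integer_forward <- function(image, rr_code, fm, strict = FALSE) {
  stopifnot(inherits(fm, "bdscnn_folded"))
  assert_binary(image); assert_binary(rr_code)
  res <- .integer_forward_batch(as_image_row(image),
                                matrix(as.integer(rr_code), nrow = 1L), fm,
                                strict = strict)
  cls <- beat_classes()[seq_len(fm$cfg$C)]
  onehot <- stats::setNames(integer(fm$cfg$C), cls)
  onehot[res$pred[1L]] <- 1L
  list(onehot = onehot, label = cls[res$pred[1L]],
       lut_values = stats::setNames(res$lut_values[1L, ], cls),
       fc2_sums = stats::setNames(res$fc2_sums[1L, ], cls))
}

#' Evaluate a folded model on a labelled dataset
#'
#' Runs integer-only inference over every beat and aggregates predictions
#' into a 5x5 confusion matrix (rows = predicted, columns = original class)
#' plus the full metric report.
#'
#' @param dataset A `beat_dataset` with labels.
#' @param fm A `bdscnn_folded` model.
#' @param mode `"layerwise"` or `"blockwise"` inference engine (results are
#'   identical; blockwise exercises the incremental datapath).
#' @return List with `confusion` (5x5 matrix), `report` (see
#'   [metric_report()]) and `pred` (predicted labels).
#' @export
evaluate_model <- function(dataset, fm, mode = c("layerwise", "blockwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "beat_dataset"))
  if (nrow(dataset$images) == 0L) stop("empty test set")
  cls <- beat_classes()[seq_len(fm$cfg$C)]
  if (mode == "layerwise") {
    res <- .integer_forward_batch(dataset$images, dataset$rr_bits, fm)
    pred <- cls[res$pred]
  } else {
    n <- nrow(dataset$images)
    pred <- character(n)
    for (i in seq_len(n)) {
      pred[i] <- blockwise_forward(
        row_to_image(dataset$images[i, ], fm$cfg$M),
        dataset$rr_bits[i, ], fm)$label
    }
  }
  cm <- confusion_matrix5(pred, dataset$label)
  list(confusion = cm, report = metric_report(cm), pred = pred)
}
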