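#' Model configuration for the bDSCNN
#'
#' Collects every architectural constant of the binarized depthwise-separable
#' network: a single-channel `M` x `M` binary input image is convolved with
#' `K` binary `KO` x `KO` kernels (stride `SO`, no batch norm, activation
#' threshold exactly 0), OR-max-pooled with a `P` x `P` window at stride `SP`,
#' passed through a depthwise (`KD` x `KD`) plus pointwise (`KP` output
#' channels) separable convolution with batch norm and binarization, and
#' finally through two fully connected layers (`F1` hidden units, `C`
#' classes). A `rr_bits`-wide binary RR-interval code is appended to the
#' flattened feature vector entering FC1.
#'
#' With the defaults the feature-map geometry is 32x32 -> 30x30x3 (conv) ->
#' 15x15x3 (pool) -> 13x13x18 (separable conv), so FC1 sees
#' `13*13*18 + rr_bits = 3046` inputs.
#'
#' @param M Input image side in pixels.
#' @param K First-layer channel (kernel) count.
#' @param KO First-layer kernel side.
#' @param SO First-layer convolution stride.
#' @param P Pooling window side.
#' @param SP Pooling stride.
#' @param KD Depthwise kernel side.
#' @param KP Pointwise output channel count.
#' @param F1 Width of the first fully connected layer.
#' @param C Number of classes.
#' @param rr_bits Width of the binary RR-interval code.
#' @param eps Batch-norm stabilizer.
#' @return An object of class `bdscnn_config` (a named list) with the
#'   arguments plus derived sizes `conv_side`, `pool_side` (`MC`), `dsc_side`
#'   (`MD`) and `fc1_inputs`.
#' @examples
#' cfg <- bdscnn_config()
#' cfg$pool_side  # 15
#' cfg$dsc_side   # 13
#' @export
bdscnn_config <- function(M = 32L, K = 3L, KO = 3L, SO = 1L, P = 2L, SP = 2L,
                          KD = 3L, KP = 18L, F1 = 32L, C = 5L, rr_bits = 4L,
                          eps = 1e-4) {
  cfg <- list(M = as.integer(M), K = as.integer(K), KO = as.integer(KO),
              SO = as.integer(SO), P = as.integer(P), SP = as.integer(SP),
              KD = as.integer(KD), KP = as.integer(KP), F1 = as.integer(F1),
              C = as.integer(C), rr_bits = as.integer(rr_bits), eps = eps)
  if (any(unlist(cfg[c("M", "K", "KO", "SO", "P", "SP", "KD", "KP", "F1",
                       "C")]) < 1L)) {
    stop("all architectural sizes must be >= 1")
  }
  conv_side <- (cfg$M - cfg$KO) / cfg$SO + 1L
  pool_side <- (conv_side - cfg$P) / cfg$SP + 1L
  dsc_side <- pool_side - cfg$KD + 1L
  if (conv_side != floor(conv_side) || pool_side != floor(pool_side) ||
      dsc_side < 1L) {
    stop("configuration does not produce integer feature-map sizes")
  }
  cfg$conv_side <- as.integer(conv_side)
  cfg$pool_side <- as.integer(pool_side)  # MC
  cfg$dsc_side <- as.integer(dsc_side)    # MD
  cfg$fc1_inputs <- cfg$dsc_side^2 * cfg$KP + cfg$rr_bits
  class(cfg) <- "bdscnn_config"
  cfg
}

#' @export
print.bdscnn_config <- function(x, ...) {
  cat("bDSCNN configuration\n")
  cat(sprintf("  input %dx%d -> conv %dx%dx%d -> pool %dx%dx%d -> dsc %dx%dx%d\n",
              x$M, x$M, x$conv_side, x$conv_side, x$K,
              x$pool_side, x$pool_side, x$K, x$dsc_side, x$dsc_side, x$KP))
  cat(sprintf("  FC1: %d -> %d, FC2: %d -> %d, RR code: %d bits\n",
              x$fc1_inputs, x$F1, x$F1, x$C, x$rr_bits))
  invisible(x)
}

#' The five AAMI beat classes
#'
#' Class labels in fixed order: non-ectopic (N), supraventricular ectopic
#' (S), ventricular ectopic (V), fusion (F) and unknown (Q). All package
#' functions use this order; argmax ties are broken toward the earliest
#' class in it.
#'
#' @return Character vector `c("N","S","V","F","Q")`.
#' @export
beat_classes <- function() c("N", "S", "V", "F", "Q")
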