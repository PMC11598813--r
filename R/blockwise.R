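# Blockwise incremental inference: instead of materializing every feature
# map, the input image is processed as MD x MD overlapping blocks, each
# flowing through MCP -> depthwise -> pointwise -> its share of the FC1
# accumulation. Integer accumulation is order-independent, so the FC1
# pre-activations -- and therefore the classification -- are bit-identical
# to the layerwise engine; what changes is intermediate storage and latency.

.block_side <- function(cfg) {
  KR <- cfg$KO + cfg$SO * (cfg$P - 1L)
  SR <- cfg$SO * cfg$SP
  as.integer(KR + SR * (cfg$KD - 1L))
}

#' Extract one input block
#'
#' Returns the square sub-image feeding the feature-extraction pipeline for
#' output position `(i, j)`: with the default geometry an 8x8 window whose
#' top-left corner is at `(2i, 2j)` (0-based).
#'
#' @param image `M` x `M` 0/1 matrix.
#' @param i,j Block row/column, 0-based, in `0..MD-1`.
#' @param cfg A `bdscnn_config`.
#' @return `block_side` x `block_side` 0/1 matrix.
#' @export
extract_block <- function(image, i, j, cfg = bdscnn_config()) {
  md <- cfg$dsc_side
  if (i < 0L || j < 0L || i > md - 1L || j > md - 1L) {
    stop("block indices must lie in 0..", md - 1L)
  }
  bs <- .block_side(cfg)
  sr <- cfg$SO * cfg$SP
  image[sr * i + seq_len(bs), sr * j + seq_len(bs), drop = FALSE]
}

# pointwise bits for a vector of K depthwise popcounts, for either a folded
# model (integer thresholds) or reference weights (real batch norm)
.pw_bits <- function(dws, model) {
  cfg <- model$cfg
  s <- as.vector(crossprod(model$pw, dws))
  if (inherits(model, "bdscnn_folded")) {
    fire <- ifelse(model$pw_fold$flipped, s < model$pw_fold$threshold,
                   s > model$pw_fold$threshold)
    as.integer(fire)
  } else {
    as.integer(.bn_apply(s, model$bn_dsc$gamma, model$bn_dsc$beta,
                         model$bn_dsc$mu, model$bn_dsc$sigma, cfg$eps) > 0)
  }
}

.model_mcpks <- function(model) {
  if (inherits(model, "bdscnn_folded")) return(model$mcpks)
  cfg <- model$cfg
  lapply(seq_len(cfg$K), function(ch) {
    build_mcpk(matrix(model$conv1[, ch], cfg$KO, cfg$KO), cfg$SO, cfg$P,
               cfg$SP)
  })
}

#' Process one block through MCP, depthwise, pointwise and FC1
#'
#' Applies the merged convolution-pooling kernels to the block (a `KD` x
#' `KD` bit grid per channel), the depthwise kernels (one popcount per
#' channel), the pointwise kernels with their binarization (integer
#' thresholds for a folded model, real batch norm for reference weights),
#' and multiplies the resulting `KP` bits into the FC1 weight rows owned by
#' feature position `(i, j)`.
#'
#' @param block Block from [extract_block()].
#' @param model A `bdscnn_folded` or `bdscnn_weights` object.
#' @param i,j Block position, 0-based.
#' @return Integer vector of `F1` partial FC1 sums.
#' @export
process_block <- function(block, model, i, j) {
  cfg <- model$cfg
  mcpks <- .model_mcpks(model)
  sr <- mcpks[[1L]]$stride
  idx_m <- conv_indices(nrow(block), nrow(mcpks[[1L]]$bits), sr)
  dws <- integer(cfg$K)
  for (ch in seq_len(cfg$K)) {
    bits <- .mcp_apply_batch(as_image_row(block), mcpks[[ch]], idx_m)
    dws[ch] <- sum(bits * model$dw[, ch])
  }
  pwb <- .pw_bits(dws, model)
  md <- cfg$dsc_side
  rows <- (seq_len(cfg$KP) - 1L) * md^2 + j * md + i + 1L
  as.integer(crossprod(model$fc1[rows, , drop = FALSE], pwb))
}

#' Blockwise FC1 pre-activations
#'
#' Accumulates [process_block()] over all `MD^2` blocks and adds the RR-code
#' rows; bit-exactly equal to the layerwise FC1 pre-activations.
#'
#' @param image `M` x `M` 0/1 matrix.
#' @param rr_code Length-`rr_bits` 0/1 vector.
#' @param model A `bdscnn_folded` or `bdscnn_weights` object.
#' @return Integer vector of `F1` sums.
#' @export
blockwise_fc1 <- function(image, rr_code, model) {
  cfg <- model$cfg
  md <- cfg$dsc_side
  acc <- integer(cfg$F1)
  for (i in 0:(md - 1L)) {
    for (j in 0:(md - 1L)) {
      acc <- acc + process_block(extract_block(image, i, j, cfg), model, i, j)
    }
  }
  rr_rows <- md^2 * cfg$KP + seq_len(cfg$rr_bits)
  acc + as.integer(crossprod(model$fc1[rr_rows, , drop = FALSE],
                             as.integer(rr_code)))
}

#' Blockwise integer-only inference
#'
#' Runs the blockwise incremental engine end to end on one image: FC1 sums
#' via [blockwise_fc1()], then folded FC1 thresholds, FC2 popcounts, lookup
#' table and argmax. Classifications are identical to [integer_forward()].
#'
#' @param image `M` x `M` 0/1 matrix.
#' @param rr_code Length-`rr_bits` 0/1 vector.
#' @param fm A `bdscnn_folded` model.
#' @return Same shape of result as [integer_forward()], plus `fc1_pre`.
#' @export
blockwise_forward <- function(image, rr_code, fm) {
  stopifnot(inherits(fm, "bdscnn_folded"))
  cfg <- fm$cfg
  fc1_pre <- blockwise_fc1(image, rr_code, fm)
  h <- .fold_fire(matrix(fc1_pre, nrow = 1L), fm$fc1_fold)
  s2 <- as.vector(h %*% fm$fc2)
  vals <- vapply(seq_len(cfg$C),
                 function(cl) fm$fc2_lut_exact[[cl]][s2[cl] + 1L], numeric(1))
  cls <- beat_classes()[seq_len(cfg$C)]
  pred <- which.max(vals)
  onehot <- stats::setNames(integer(cfg$C), cls)
  onehot[pred] <- 1L
  list(onehot = onehot, label = cls[pred],
       lut_values = stats::setNames(vals, cls),
       fc2_sums = stats::setNames(s2, cls), fc1_pre = fc1_pre)
}

#' Analytic latency model
#'
#' Cycle counts under the execution model in which each listed micro-step
#' costs one cycle: the layerwise latency is
#' `L = MC^2 + 2*MD^2 + KP*MD^2` (convolution positions, depthwise and
#' pointwise positions, and `KP` FC1 passes per position), the un-pipelined
#' blockwise latency is `LB = (KD^2 + 1 + 1 + KP) * MD^2`, and overlapping
#' the next block's feature extraction with the current FC1 work collapses
#' it to `LB_pipelined = KP * MD^2`. Reported numbers are model cycles, not
#' wall-clock time, and exclude control overhead.
#'
#' @param cfg A `bdscnn_config`.
#' @return Object of class `latency_report`: list with `MC`, `MD`, `L`,
#'   `LB`, `LB_pipelined` and `n_blocks`.
#' @examples
#' latency_report(bdscnn_config())  # L 3605, LB 4901, pipelined 3042
#' @export
latency_report <- function(cfg = bdscnn_config()) {
  KR <- cfg$KO + cfg$SO * (cfg$P - 1L)
  SR <- cfg$SO * cfg$SP
  mc <- (cfg$M - KR) / SR + 1L
  if (mc != cfg$pool_side) {
    stop("geometry mismatch: merged-kernel map side ", mc,
         " != pooled map side ", cfg$pool_side)
  }
  md <- cfg$dsc_side
  structure(list(MC = as.integer(mc), MD = md,
                 L = as.integer(mc^2 + 2L * md^2 + cfg$KP * md^2),
                 LB = as.integer((cfg$KD^2 + 2L + cfg$KP) * md^2),
                 LB_pipelined = as.integer(cfg$KP * md^2),
                 n_blocks = as.integer(md^2)),
            class = "latency_report")
}

#' @export
print.latency_report <- function(x, ...) {
  cat(sprintf("latency: layerwise %d, blockwise %d, pipelined %d cycles (%d blocks, MC=%d, MD=%d)\n",
              x$L, x$LB, x$LB_pipelined, x$n_blocks, x$MC, x$MD))
  invisible(x)
}

#' Intermediate-storage model
#'
#' Per-stage intermediate storage (element counts) of layerwise versus
#' blockwise execution: the layerwise engine materializes the input image,
#' the pooled maps, the depthwise maps, the separable-convolution output
#' and the FC1 input vector, while the blockwise engine holds only one
#' input block, one `KD x KD x K` merged-kernel output, `K` depthwise
#' popcounts, `KP` pointwise bits and `KP` staged values.
#'
#' @param cfg A `bdscnn_config`.
#' @return List with `layerwise`, `blockwise` (named integer vectors),
#'   `layerwise_total`, `blockwise_total` and `ratio`.
#' @export
storage_report <- function(cfg = bdscnn_config()) {
  bs <- .block_side(cfg)
  lay <- c(input = cfg$M^2, pooled = cfg$pool_side^2 * cfg$K,
           dw = cfg$dsc_side^2 * cfg$K, dsc = cfg$dsc_side^2 * cfg$KP,
           fc1_in = cfg$dsc_side^2 * cfg$KP)
  blk <- c(input = bs^2, mcp = cfg$KD^2 * cfg$K, dw = cfg$K, dsc = cfg$KP,
           fc1_in = cfg$KP)
  list(layerwise = lay, blockwise = blk,
       layerwise_total = sum(lay), blockwise_total = sum(blk),
       ratio = sum(lay) / sum(blk))
}
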