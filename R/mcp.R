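# Merged convolution-pooling (MCP) kernel algebra.
#
# For 0/1 data and weights with an activation threshold of exactly 0,
# binarize(popcount(window AND kernel)) is the OR of (window AND kernel),
# and OR-pooling over P x P shifted convolution outputs equals a single
# convolution with one enlarged kernel built by OR-ing P^2 shifted copies of
# the original: conv -> binarize -> OR-pool collapses into one pass. The
# merge is only valid at threshold 0; it must not be applied after a folded
# (nonzero-threshold) activation.

#' Build a merged convolution-pooling kernel
#'
#' OR-merges `P^2` copies of a binary kernel, shifted by the convolution
#' stride, into one enlarged kernel of side `KR = KO + SO*(P-1)` applied at
#' stride `SR = SO*SP`. The original kernel's top-left cell anchors at the
#' merged frame's top-left; shifts go down/right.
#'
#' @param kernel 0/1 `KO` x `KO` matrix.
#' @param SO Original convolution stride.
#' @param P Pooling window side.
#' @param SP Pooling stride.
#' @param activation_threshold Integer threshold of the activation between
#'   the convolution and the pool being merged. The OR-merge identity only
#'   holds at threshold 0 (any positive popcount fires); merging across a
#'   folded batch-norm activation with a nonzero threshold is invalid and
#'   rejected.
#' @return An object of class `mcp_kernel`: list with `bits` (`KR` x `KR`
#'   0/1 matrix), `stride` (`SR`), `source` (the inputs) and
#'   `nonzero_count`.
#' @examples
#' k <- matrix(0L, 3, 3); k[2, 2] <- 1L
#' build_mcpk(k, 1, 2, 2)$bits  # 1s exactly at rows/cols 2:3
#' @export
build_mcpk <- function(kernel, SO = 1L, P = 2L, SP = 2L,
                       activation_threshold = 0L) {
  assert_binary(kernel)
  if (activation_threshold != 0L) {
    stop("convolution-pooling merge is only valid for an activation ",
         "threshold of 0: binarize(popcount > ", activation_threshold,
         ") does not distribute over OR, so this layer cannot be merged")
  }
  stopifnot(nrow(kernel) == ncol(kernel), nrow(kernel) >= 1L,
            SO >= 1L, P >= 1L, SP >= 1L)
  KO <- nrow(kernel)
  KR <- KO + SO * (P - 1L)
  bits <- matrix(0L, KR, KR)
  for (dr in 0:(P - 1L)) {
    for (dc in 0:(P - 1L)) {
      rows <- SO * dr + seq_len(KO)
      cols <- SO * dc + seq_len(KO)
      bits[rows, cols] <- pmax(bits[rows, cols], kernel)
    }
  }
  structure(list(bits = bits, stride = as.integer(SO * SP),
                 source = list(kernel = kernel, SO = as.integer(SO),
                               P = as.integer(P), SP = as.integer(SP)),
                 nonzero_count = sum(bits)),
            class = "mcp_kernel")
}

#' @export
print.mcp_kernel <- function(x, ...) {
  cat(sprintf("mcp_kernel %dx%d, stride %d, %d/%d nonzero\n", nrow(x$bits),
              ncol(x$bits), x$stride, x$nonzero_count, length(x$bits)))
  for (r in seq_len(nrow(x$bits))) cat(" ", paste(x$bits[r, ], collapse = ""),
                                       "\n")
  invisible(x)
}

#' Prune zero weights of an MCP kernel
#'
#' Positions whose merged weight is 0 cannot affect an OR-reduction, so the
#' kernel reduces to its list of 1-positions; applying only these positions
#' reproduces [mcp_apply()] exactly.
#'
#' @param mcpk An `mcp_kernel`.
#' @return Integer matrix with columns `row`, `col` (1-based positions of the
#'   1-bits, column-major order); `nonzero_count` rows.
#' @export
prune <- function(mcpk) {
  stopifnot(inherits(mcpk, "mcp_kernel"))
  pos <- which(mcpk$bits == 1L, arr.ind = TRUE)
  colnames(pos) <- c("row", "col")
  pos
}

.mcp_apply_batch <- function(X, mcpk, idx) {
  (conv_batch(X, as.integer(mcpk$bits), idx) > 0) * 1L
}

#' Apply an MCP kernel in a single pass
#'
#' Each output bit is the OR, over the kernel's 1-positions, of the image
#' bits under the kernel placed at stride `SR`; bit-exactly equal to
#' convolving with the source kernel, binarizing at threshold 0 and
#' OR-pooling.
#'
#' @param image 0/1 matrix, side at least `KR`.
#' @param mcpk An `mcp_kernel`.
#' @return 0/1 integer matrix of side `(side - KR)/SR + 1`.
#' @export
mcp_apply <- function(image, mcpk) {
  stopifnot(inherits(mcpk, "mcp_kernel"))
  assert_binary(image)
  if (nrow(image) < nrow(mcpk$bits)) stop("image smaller than MCP kernel")
  idx <- conv_indices(nrow(image), nrow(mcpk$bits), mcpk$stride)
  row_to_image(.mcp_apply_batch(as_image_row(image), mcpk, idx),
               attr(idx, "out_side"))
}

#' First-layer operation counts with and without MCP
#'
#' Closed-form operation counts for the first convolution-plus-pooling
#' stage: the merged single-pass variant costs `MC^2 * K * KR^2` AND
#' operations unpruned (or `MC^2` times the summed nonzero counts when
#' pruned kernels are supplied), against a sequential baseline of
#' `conv_side^2 * K * KO^2` convolution ANDs plus 2 operations per `P` x `P`
#' pooling window (`MC^2 * K * 2`) -- the pooling-cost convention under
#' which the printed baseline totals are consistent.
#'
#' @param cfg A `bdscnn_config`.
#' @param variant `"mcp"` (unpruned merged), `"baseline"` (sequential
#'   conv + pool) or `"pruned"` (merged, zero weights skipped).
#' @param mcpks List of `mcp_kernel`s, required for `variant = "pruned"`.
#' @return Integer operation count.
#' @examples
#' mcp_op_count(bdscnn_config(), "mcp")      # 10800
#' mcp_op_count(bdscnn_config(), "baseline") # 25650
#' @export
mcp_op_count <- function(cfg = bdscnn_config(),
                         variant = c("mcp", "baseline", "pruned"),
                         mcpks = NULL) {
  variant <- match.arg(variant)
  KR <- cfg$KO + cfg$SO * (cfg$P - 1L)
  MC <- cfg$pool_side
  switch(variant,
    mcp = MC^2 * cfg$K * KR^2,
    baseline = cfg$conv_side^2 * cfg$K * cfg$KO^2 + MC^2 * cfg$K * 2L,
    pruned = {
      if (is.null(mcpks)) stop("pruned variant needs the MCP kernels")
      MC^2 * sum(vapply(mcpks, function(k) k$nonzero_count, integer(1)))
    })
}

#' Verify the merge equivalence on a stack of images
#'
#' Runs both routes -- the single-pass merged kernel, and the sequential
#' convolution, 0,1 binarization at threshold 0, OR-pool pipeline -- over a
#' stack of binary images and counts bitwise disagreements (which should
#' always be zero).
#'
#' @param images n x `side^2` 0/1 matrix of column-major flattened images.
#' @param side Image side.
#' @param kernels List of 0/1 `KO` x `KO` kernel matrices.
#' @param SO,P,SP First-layer geometry (convolution stride, pool side, pool
#'   stride).
#' @return List with `n_checked` (image-kernel output bits compared) and
#'   `mismatches`.
#' @export
check_mcp_equivalence <- function(images, side, kernels, SO = 1L, P = 2L,
                                  SP = 2L) {
  stopifnot(is.matrix(images), ncol(images) == side^2)
  KO <- nrow(kernels[[1L]])
  KR <- KO + SO * (P - 1L)
  conv_side <- (side - KO) %/% SO + 1L
  idx_m <- conv_indices(side, KR, SO * SP)
  idx_c <- conv_indices(side, KO, SO)
  idx_p <- conv_indices(conv_side, P, SP)
  checked <- 0L
  bad <- 0L
  for (kern in kernels) {
    mcpk <- build_mcpk(kern, SO, P, SP)
    merged <- .mcp_apply_batch(images, mcpk, idx_m)
    layered <- pool_batch((conv_batch(images, as.integer(kern), idx_c) > 0) * 1L,
                          idx_p)
    checked <- checked + length(merged)
    bad <- bad + sum(merged != layered)
  }
  list(n_checked = checked, mismatches = bad)
}

#' Enumerate every binary image of a given side
#'
#' @param side Image side; `side^2` must be at most 16 (65,536 images).
#' @return `2^(side^2)` x `side^2` 0/1 matrix, one image per row
#'   (column-major flattened).
#' @export
enumerate_binary_images <- function(side) {
  nbits <- side^2
  if (nbits > 16) stop("enumeration capped at 16 pixels")
  n <- 2^nbits
  vals <- 0:(n - 1)
  out <- matrix(0L, n, nbits)
  for (b in seq_len(nbits)) {
    out[, b] <- bitwAnd(vals, 2^(b - 1)) > 0
  }
  storage.mode(out) <- "integer"
  out
}
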