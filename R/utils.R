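#' @keywords internal
"_PACKAGE"

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_binary <- function(x) all(x == 0L | x == 1L)

assert_binary <- function(x, what = deparse(substitute(x))) {
  if (!is_binary(x)) stop(what, " must contain only 0/1 values", call. = FALSE)
  invisible(TRUE)
}

# Flattened (column-major) indices of the k x k patch anchored at each valid
# output position of a `side` x `side` image convolved with stride `stride`.
# Rows: output positions in column-major order (so the output rows themselves
# form a column-major flattened out x out image and stages chain); cols:
# kernel cells in column-major (within-kernel) order.
conv_indices <- function(side, k, stride = 1L) {
  out <- (side - k) / stride + 1L
  if (out != floor(out) || out < 1L) {
    stop("invalid geometry: side ", side, ", kernel ", k, ", stride ", stride,
         call. = FALSE)
  }
  out <- as.integer(out)
  pos <- expand.grid(r = seq_len(out), c = seq_len(out))  # column-major output
  ker <- expand.grid(kr = seq_len(k), kc = seq_len(k))    # column-major kernel
  idx <- matrix(0L, nrow = out * out, ncol = k * k)
  for (t in seq_len(k * k)) {
    rr <- (pos$r - 1L) * stride + ker$kr[t]
    cc <- (pos$c - 1L) * stride + ker$kc[t]
    idx[, t] <- (cc - 1L) * side + rr
  }
  attr(idx, "out_side") <- out
  idx
}

# Batched popcount convolution: X is n x side^2 (rows = flattened images,
# column-major), kern a k^2 vector (column-major). Returns n x out^2 integer
# matrix of popcounts, output positions row-major.
conv_batch <- function(X, kern, idx) {
  n <- nrow(X)
  acc <- matrix(0L, n, nrow(idx))
  for (t in which(kern != 0)) {
    acc <- acc + X[, idx[, t], drop = FALSE]
  }
  acc
}

# Batched OR-pooling over precomputed window indices (n x out^2 binary out).
pool_batch <- function(B, idx) {
  out <- B[, idx[, 1L], drop = FALSE]
  for (t in 2L:ncol(idx)) {
    out <- pmax(out, B[, idx[, t], drop = FALSE])
  }
  out
}

# Flatten a single image matrix to the 1 x side^2 batch representation.
as_image_row <- function(image) {
  if (!is.matrix(image)) stop("image must be a matrix", call. = FALSE)
  matrix(as.integer(image), nrow = 1L)
}

row_to_image <- function(row, side) {
  matrix(as.integer(row), nrow = side, ncol = side)
}
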