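# Preprocessing: beat segmentation, beat-to-image rasterization, z-score
# augmentation, RR-interval coding and dataset splitting.

.subset_beats <- function(bs, idx) {
  structure(list(samples = bs$samples[idx, , drop = FALSE],
                 rr_prev = bs$rr_prev[idx], label = bs$label[idx],
                 record_id = bs$record_id[idx], fs = bs$fs,
                 rr_median = bs$rr_median),
            class = "beat_set")
}

.bind_beats <- function(a, b) {
  structure(list(samples = rbind(a$samples, b$samples),
                 rr_prev = c(a$rr_prev, b$rr_prev),
                 label = c(a$label, b$label),
                 record_id = c(a$record_id, b$record_id), fs = a$fs,
                 rr_median = a$rr_median),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  tab <- table(factor(x$label, levels = beat_classes()))
  cat(sprintf("beat_set: %d beats (%s), %d record(s)\n", nrow(x$samples),
              paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                    collapse = " "), length(unique(x$record_id))))
  invisible(x)
}

#' Segment an annotated record into fixed-length beats
#'
#' Cuts one 300-sample window (at 360 Hz; scaled for other rates) around
#' every annotated R peak that has at least 100 samples of left and 200
#' samples of right context -- peaks too close to the record edges are
#' skipped and their count reported via a message. The preceding RR interval
#' of each beat is computed from consecutive annotated peaks; the first beat
#' of a record, which has no predecessor, is assigned the record's median RR.
#'
#' @param record An `ecg_record` (from [generate_record()] or
#'   [read_record_csv()]).
#' @return A `beat_set`: list with `samples` (n x 300 matrix), `rr_prev`
#'   (seconds), `label`, `record_id`, `fs` and `rr_median` (seconds).
#' @examples
#' rec <- generate_record(20, rep(0.2, 5), rng_seed = 1)
#' segment_beats(rec)
#' @export
segment_beats <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$r_peaks) < 1L) stop("record has no annotated R peaks")
  scale <- record$fs / 360
  left <- as.integer(100 * scale)
  right <- as.integer(200 * scale)
  n <- length(record$samples)
  ok <- (record$r_peaks - 1L) >= left & (n - record$r_peaks) >= right
  if (any(!ok)) {
    message(sum(!ok), " beat(s) skipped: insufficient context")
  }
  peaks <- record$r_peaks[ok]
  if (length(peaks) == 0L) stop("no segmentable beats in record")
  rr_all <- diff(record$r_peaks) / record$fs
  rr_med <- if (length(rr_all)) stats::median(rr_all) else NA_real_
  # rr_prev indexed on the full annotation list, then restricted
  rr_prev_all <- c(rr_med, rr_all)
  win <- as.integer(left + right)
  samples <- matrix(0, length(peaks), win)
  for (k in seq_along(peaks)) {
    samples[k, ] <- record$samples[(peaks[k] - left):(peaks[k] + right - 1L)]
  }
  structure(list(samples = samples, rr_prev = rr_prev_all[ok],
                 label = record$labels[ok],
                 record_id = rep(record$record_id, length(peaks)),
                 fs = record$fs, rr_median = rr_med),
            class = "beat_set")
}

#' Segment several records into one beat set
#'
#' @param records List of `ecg_record` objects.
#' @return A combined `beat_set`; `rr_median` is the per-record median RR of
#'   the first record (per-beat RR codes are normalized per record, see
#'   [build_dataset()]).
#' @export
segment_records <- function(records) {
  sets <- lapply(records, segment_beats)
  Reduce(.bind_beats, sets)
}

#' Rasterize a beat into a binarized image
#'
#' Renders the 300-sample trace as a 1-pixel connected polyline on a
#' `4*side` x 300 canvas (amplitude normalized so the minimum maps to the
#' bottom row and the maximum to the top row; a flat trace maps to the middle
#' row), then downscales to `side` x `side` by block-max: any block that
#' contains a trace pixel becomes 1. Block-max preserves the thin trace that
#' area-averaging would erase at low resolution. The result is deterministic.
#'
#' @param samples Numeric vector of beat amplitudes (one beat window).
#' @param side Output image side in pixels (>= 8).
#' @return `side` x `side` integer 0/1 matrix (row 1 is the top).
#' @examples
#' img <- beat_to_image(generate_beat("N", 1))
#' dim(img)
#' @export
beat_to_image <- function(samples, side = 32L) {
  if (is.list(samples)) stop("samples must be a numeric vector")
  side <- as.integer(side)
  if (side < 8L) stop("side must be >= 8 (below minimum feature resolution)")
  n <- length(samples)
  if (n < 2L) stop("a beat needs at least 2 samples")
  H <- 4L * side
  rng <- max(samples) - min(samples)
  y <- if (rng < 1e-12) {
    rep(H %/% 2L, n)                       # flat trace: single middle row
  } else {
    as.integer(round((max(samples) - samples) / rng * (H - 1L))) + 1L
  }
  canvas <- matrix(0L, H, n)
  canvas[cbind(y, seq_len(n))] <- 1L
  # connect consecutive samples with a vertical span in the later column
  for (i in 2L:n) {
    if (y[i] != y[i - 1L]) {
      canvas[min(y[i - 1L], y[i]):max(y[i - 1L], y[i]), i] <- 1L
    }
  }
  # block-max downscale: rows in blocks of 4, columns in floor-spaced blocks
  rb <- matrix(0L, side, n)
  for (r in seq_len(side)) {
    base <- (r - 1L) * 4L
    rb[r, ] <- pmax(canvas[base + 1L, ], canvas[base + 2L, ],
                    canvas[base + 3L, ], canvas[base + 4L, ])
  }
  cb <- floor((seq_len(n) - 1L) * side / n) + 1L
  out <- matrix(0L, side, side)
  for (c in seq_len(side)) {
    cols <- which(cb == c)
    out[, c] <- if (length(cols) == 1L) rb[, cols] else
      do.call(pmax, as.data.frame(rb[, cols]))
  }
  structure(out, class = c("binary_image", class(out)))
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("binary_image %dx%d (%d set pixels)\n", nrow(x), ncol(x),
              sum(x)))
  invisible(x)
}

#' Quantize a normalized RR interval to an unsigned binary code
#'
#' The preceding RR interval, normalized by the record's median RR, is
#' quantized to `round(ratio * 8)` clamped to the `bits`-wide unsigned range,
#' so the nominal beat-to-beat interval (ratio 1) maps to code 8 and the
#' shortened interval typical of supraventricular ectopy (ratio about 0.6)
#' maps to code 5.
#'
#' @param ratio `rr_prev / median RR` (missing values map to 1).
#' @param bits Code width.
#' @return Integer code in `[0, 2^bits - 1]`.
#' @export
rr_quantize <- function(ratio, bits = 4L) {
  ratio[!is.finite(ratio)] <- 1
  pmin(pmax(as.integer(round(ratio * 8)), 0L), as.integer(2^bits - 1L))
}

.code_to_bits <- function(code, bits) {
  vapply(seq_len(bits), function(b) as.integer(bitwAnd(code, 2L^(b - 1L)) > 0L),
         integer(length(code)))
}

#' Balance classes by z-score augmentation
#'
#' For every class with fewer than `target_per_class` beats, synthesizes new
#' beats as `x' = sigma' * z + mu'`, where `z` is the z-scored source beat
#' and `(mu', sigma')` are seeded perturbations of the source mean and
#' standard deviation (`mu'` uniform in `mu +/- 0.1*sigma`, `sigma'` uniform
#' in `sigma * [0.9, 1.1]`). Source beats are drawn with replacement from the
#' class; originals are retained unmodified; classes at or above the target
#' are left unchanged (no subsampling). Intended for training partitions
#' only -- never augment validation or test data.
#'
#' @param beats A `beat_set`.
#' @param target_per_class Desired beat count per class present in `beats`.
#' @param rng_seed Integer seed.
#' @return A `beat_set` with every present class at
#'   `max(target_per_class, original count)` beats.
#' @export
zscore_augment <- function(beats, target_per_class, rng_seed) {
  stopifnot(inherits(beats, "beat_set"))
  with_seed(rng_seed, {
    out <- beats
    for (cls in intersect(beat_classes(), unique(beats$label))) {
      idx <- which(beats$label == cls)
      need <- target_per_class - length(idx)
      if (need <= 0L) next
      src <- sample(idx, need, replace = TRUE)
      newx <- matrix(0, need, ncol(beats$samples))
      for (k in seq_len(need)) {
        x <- beats$samples[src[k], ]
        m <- mean(x); s <- stats::sd(x)
        z <- if (s > 0) (x - m) / s else x * 0
        m2 <- m + stats::runif(1, -0.1 * s, 0.1 * s)
        s2 <- s * stats::runif(1, 0.9, 1.1)
        newx[k, ] <- s2 * z + m2
      }
      add <- structure(list(samples = newx, rr_prev = beats$rr_prev[src],
                            label = rep(cls, need),
                            record_id = beats$record_id[src], fs = beats$fs,
                            rr_median = beats$rr_median),
                       class = "beat_set")
      out <- .bind_beats(out, add)
    }
    out
  })
}

#' Construct a dataset split specification
#'
#' @param scheme `"patient_specific"` (split within each record: `fractions[1]`
#'   of the beats to train, then the remainder to validation/test at the
#'   stated fractions) or `"patient_wise"` (whole records assigned to exactly
#'   one partition).
#' @param fractions Train/validation/test fractions, summing to 1; the
#'   default 0.70/0.09/0.21 corresponds to 70% train and a 30%/70%
#'   validation/test split of the remainder.
#' @param rng_seed Integer seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(scheme = c("patient_specific", "patient_wise"),
                       fractions = c(0.70, 0.09, 0.21), rng_seed = 0L) {
  scheme <- match.arg(scheme)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be 3 nonnegative values summing to 1")
  }
  structure(list(scheme = scheme, fractions = fractions,
                 rng_seed = as.integer(rng_seed)), class = "split_spec")
}

#' Split a beat set into train/validation/test partitions
#'
#' Under `patient_specific`, each record's beats are shuffled and divided at
#' the specified fractions (integer rounding per record); a record with
#' fewer than 2 beats goes entirely to train with a warning. Under
#' `patient_wise`, whole records are assigned to one partition each, in
#' shuffled order, until the cumulative beat counts reach the fractions.
#' Partitions are disjoint and the split is deterministic given the seed.
#'
#' @param beats A `beat_set`.
#' @param spec A `split_spec`.
#' @return Named list of `beat_set`s: `train`, `val`, `test` (the latter two
#'   may be empty for degenerate inputs).
#' @export
split_dataset <- function(beats, spec) {
  stopifnot(inherits(beats, "beat_set"), inherits(spec, "split_spec"))
  n <- nrow(beats$samples)
  if (n < 1L) stop("beats must be non-empty")
  f <- spec$fractions
  with_seed(spec$rng_seed, {
    tr <- integer(0); va <- integer(0); te <- integer(0)
    if (spec$scheme == "patient_specific") {
      for (rid in unique(beats$record_id)) {
        idx <- which(beats$record_id == rid)
        m <- length(idx)
        if (m < 2L) {
          warning("record ", rid, " has fewer than 2 beats; all to train")
          tr <- c(tr, idx)
          next
        }
        idx <- sample(idx)
        n_tr <- round(f[1] * m)
        n_va <- round(f[2] * m)
        tr <- c(tr, idx[seq_len(n_tr)])
        va <- c(va, idx[n_tr + seq_len(n_va)])
        te <- c(te, idx[setdiff(seq_len(m), seq_len(n_tr + n_va))])
      }
    } else {
      rids <- sample(unique(beats$record_id))
      counts <- vapply(rids, function(r) sum(beats$record_id == r), integer(1))
      cum <- cumsum(counts) / n
      part <- ifelse(cum <= f[1] + 1e-12, 1L,
                     ifelse(cum <= f[1] + f[2] + 1e-12, 2L, 3L))
      # guarantee at least one record in train
      if (all(part != 1L)) part[1L] <- 1L
      for (i in seq_along(rids)) {
        idx <- which(beats$record_id == rids[i])
        if (part[i] == 1L) tr <- c(tr, idx)
        else if (part[i] == 2L) va <- c(va, idx)
        else te <- c(te, idx)
      }
    }
    list(train = .subset_beats(beats, sort(tr)),
         val = .subset_beats(beats, sort(va)),
         test = .subset_beats(beats, sort(te)))
  })
}

#' Build a model-ready dataset from a beat set
#'
#' Rasterizes every beat (see [beat_to_image()]) and quantizes its RR
#' interval, normalized by the per-record median RR, into the binary code
#' appended to the FC1 input.
#'
#' @param beats A `beat_set`.
#' @param cfg A `bdscnn_config`.
#' @return A `beat_dataset`: list with `images` (n x `M^2` 0/1 matrix,
#'   column-major flattened), `rr_bits` (n x `rr_bits` 0/1 matrix), `rr_int`
#'   (integer codes), `label`, `record_id`, `side`.
#' @export
build_dataset <- function(beats, cfg = bdscnn_config()) {
  stopifnot(inherits(beats, "beat_set"))
  n <- nrow(beats$samples)
  images <- matrix(0L, n, cfg$M^2)
  for (k in seq_len(n)) {
    images[k, ] <- as.integer(beat_to_image(beats$samples[k, ], cfg$M))
  }
  # normalize RR by per-record median RR
  ratio <- beats$rr_prev
  for (rid in unique(beats$record_id)) {
    idx <- which(beats$record_id == rid)
    med <- stats::median(beats$rr_prev[idx], na.rm = TRUE)
    ratio[idx] <- beats$rr_prev[idx] / med
  }
  code <- rr_quantize(ratio, cfg$rr_bits)
  structure(list(images = images,
                 rr_bits = matrix(.code_to_bits(code, cfg$rr_bits), nrow = n),
                 rr_int = code, label = beats$label,
                 record_id = beats$record_id, side = cfg$M),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  tab <- table(factor(x$label, levels = beat_classes()))
  cat(sprintf("beat_dataset: %d images %dx%d (%s)\n", nrow(x$images), x$side,
              x$side, paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                            collapse = " ")))
  invisible(x)
}
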