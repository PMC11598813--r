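test_that("segmentation takes 100 left / 200 right samples around each peak", {
  x <- seq_len(600) / 600
  rec <- manual_record(x, r_peaks = 151L, labels = "N")  # 0-based index 150
  bs <- segment_beats(rec)
  expect_identical(nrow(bs$samples), 1L)
  expect_equal(bs$samples[1, ], x[51:350])  # 0-based 50..349

  # insufficient left context: skipped with a message
  rec2 <- manual_record(x, r_peaks = c(51L, 300L), labels = c("N", "V"))
  expect_message(bs2 <- segment_beats(rec2), "skipped")
  expect_identical(bs2$label, "V")

  expect_error(segment_beats(manual_record(x, integer(0), character(0))),
               "no annotated R peaks")
})

test_that("rr_prev comes from consecutive peaks at the sampling rate", {
  x <- rnorm(1000)
  rec <- manual_record(x, r_peaks = c(101L, 461L, 700L),
                       labels = c("N", "N", "N"))
  bs <- segment_beats(rec)
  expect_equal(bs$rr_prev[2], 1.0)          # 360 samples / 360 Hz
  expect_equal(bs$rr_prev[3], 239 / 360)
  # first beat takes the record median RR
  expect_equal(bs$rr_prev[1], median(c(1.0, 239 / 360)))
})

test_that("beat images are binary, deterministic and trace-preserving", {
  b <- generate_beat("N", 4)
  img <- beat_to_image(b)
  expect_identical(dim(img), c(32L, 32L))
  expect_true(all(img %in% 0:1))
  expect_gt(sum(img), 0)
  expect_identical(unclass(img), unclass(beat_to_image(b)))
  expect_error(beat_to_image(b, side = 4), "side")
})

test_that("a flat-line beat renders as a single horizontal row", {
  img <- beat_to_image(rep(2.5, 300))
  # every column has exactly one set pixel, all in the same row
  expect_true(all(colSums(img) == 1))
  expect_length(unique(apply(img, 2, which.max)), 1L)
})

test_that("z-score augmentation reaches the target counts, keeps originals", {
  rec <- generate_record(200, c(0.9, 0, 0.1, 0, 0), rng_seed = 2)
  bs <- segment_beats(rec)
  n_n <- sum(bs$label == "N")
  n_v <- sum(bs$label == "V")
  target <- n_n
  aug <- zscore_augment(bs, target, rng_seed = 7)
  expect_identical(sum(aug$label == "N"), n_n)       # untouched (at target)
  expect_identical(sum(aug$label == "V"), target)    # filled up
  # originals retained unmodified, in place
  expect_equal(aug$samples[seq_len(nrow(bs$samples)), ], bs$samples)
  # synthesized beats stay close to their sources in mean/sd
  new_idx <- which(aug$label == "V")[-seq_len(n_v)]
  m <- rowMeans(aug$samples[new_idx, , drop = FALSE])
  s <- apply(aug$samples[new_idx, , drop = FALSE], 1, sd)
  src_s <- apply(bs$samples[bs$label == "V", , drop = FALSE], 1, sd)
  expect_true(all(s >= 0.9 * min(src_s) & s <= 1.1 * max(src_s)))
  expect_true(all(abs(m - mean(bs$samples[bs$label == "V", ])) <
                    0.2 * max(src_s) + 0.05))
  # a target below the existing count changes nothing
  expect_identical(zscore_augment(bs, 1, rng_seed = 7)$label, bs$label)
})

test_that("patient-specific split gives 70/9/21 on a 100-beat record", {
  rec <- generate_record(100, rep(0.2, 5), rng_seed = 6)
  bs <- segment_beats(rec)
  sp <- split_spec("patient_specific", rng_seed = 0)
  parts <- split_dataset(bs, sp)
  expect_identical(vapply(parts, function(p) length(p$label), integer(1)),
                   c(train = 70L, val = 9L, test = 21L))
  # determinism and disjointness
  parts2 <- split_dataset(bs, sp)
  expect_identical(parts$train$samples, parts2$train$samples)
  expect_identical(parts$test$label, parts2$test$label)
})

test_that("patient-wise split never divides a record", {
  records <- lapply(1:10, function(r) {
    generate_record(30, rep(0.2, 5), rng_seed = 100 + r,
                    record_id = paste0("rec", r))
  })
  bs <- segment_records(records)
  parts <- split_dataset(bs, split_spec("patient_wise", rng_seed = 1))
  ids <- lapply(parts, function(p) unique(p$record_id))
  expect_length(intersect(ids$train, ids$val), 0L)
  expect_length(intersect(ids$train, ids$test), 0L)
  expect_length(intersect(ids$val, ids$test), 0L)
  expect_setequal(unlist(ids), paste0("rec", 1:10))
})

test_that("split specifications are validated", {
  expect_error(split_spec(fractions = c(0.5, 0.4, 0.3)), "summing to 1")
  rec <- generate_record(5, rep(0.2, 5), rng_seed = 1)
  bs <- segment_beats(rec)
  single <- bitbeat:::.subset_beats(bs, 1L)
  expect_warning(split_dataset(single, split_spec()), "fewer than 2 beats")
})

test_that("RR quantization maps nominal and shortened intervals apart", {
  expect_identical(rr_quantize(1), 8L)
  expect_identical(rr_quantize(0.6), 5L)
  expect_identical(rr_quantize(10), 15L)   # clamped
  expect_identical(rr_quantize(NA), 8L)    # missing -> nominal
  ds <- build_dataset(segment_beats(generate_record(30, rep(0.2, 5), 9)))
  expect_identical(dim(ds$rr_bits), c(30L, 4L))
  expect_true(all(ds$rr_bits %in% 0:1))
  # bits encode the integer code, LSB first
  code <- as.integer(ds$rr_bits %*% 2^(0:3))
  expect_identical(code, ds$rr_int)
})
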