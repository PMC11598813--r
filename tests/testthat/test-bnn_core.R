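test_that("binarization follows the strict-positive rule and is idempotent", {
  expect_identical(binarize(c(-2, 0, 0.5)), c(0L, 0L, 1L))
  x <- rnorm(100)
  expect_identical(binarize(binarize(x)), binarize(x))
  m <- matrix(rnorm(9), 3)
  expect_identical(dim(binarize(m)), dim(m))
})

test_that("binary convolution matches an exhaustive nested-loop oracle", {
  set.seed(21)
  # shape contract of the first layer
  out <- bconv_valid(random_image(32), random_bits(3, 3))
  expect_identical(dim(out), c(30L, 30L))
  expect_true(all(bconv_valid(random_image(8), matrix(0L, 3, 3)) == 0L))
  expect_error(bconv_valid(random_image(2), random_bits(3, 3)), "larger")

  # brute-force popcount oracle on random 5x5 images
  for (rep in 1:20) {
    img <- random_image(5, 0.5)
    k <- random_bits(3, 3)
    got <- bconv_valid(img, k)
    want <- matrix(0L, 3, 3)
    for (r in 1:3) for (c in 1:3) {
      acc <- 0L
      for (i in 1:3) for (j in 1:3) {
        acc <- acc + img[r + i - 1, c + j - 1] * k[i, j]
      }
      want[r, c] <- acc
    }
    expect_identical(got, want)
  }
})

test_that("conv and OR-pool agree with enumeration over every 4x4 image", {
  set.seed(77)
  IM <- enumerate_binary_images(4)
  k <- random_bits(3, 3)
  kvec <- as.integer(k)
  # independent oracle: direct popcount per output position over the stack
  oracle_conv <- matrix(0L, nrow(IM), 4)
  pos <- 0L
  for (cc in 1:2) for (rr in 1:2) {
    pos <- pos + 1L
    acc <- integer(nrow(IM))
    for (j in 1:3) for (i in 1:3) {
      acc <- acc + IM[, (cc + j - 2) * 4 + (rr + i - 1)] * k[i, j]
    }
    oracle_conv[, pos] <- acc
  }
  oracle_pool <- as.integer(rowSums(oracle_conv > 0) > 0)
  # package functions against the oracle on a stride through all images,
  # covering conv popcounts and the pooled bit
  got_pool <- integer(0)
  for (row in seq(1, nrow(IM), by = 61)) {
    img <- matrix(IM[row, ], 4, 4)
    expect_identical(as.integer(bconv_valid(img, k)), oracle_conv[row, ])
    got_pool <- c(got_pool,
                  as.integer(or_maxpool(binarize(bconv_valid(img, k)), 2, 2)))
  }
  expect_identical(got_pool, oracle_pool[seq(1, nrow(IM), by = 61)])
})

test_that("OR-pooling equals a max filter", {
  set.seed(5)
  g <- random_image(30, 0.4)
  p <- or_maxpool(g, 2, 2)
  expect_identical(dim(p), c(15L, 15L))
  for (r in 1:15) for (c in 1:15) {
    expect_identical(p[r, c], max(g[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c)]))
  }
  expect_true(all(or_maxpool(matrix(1L, 8, 8)) == 1L))
})

test_that("separable convolution equals rank-1 conventional convolution", {
  set.seed(31)
  cfg <- bdscnn_config()
  maps <- array(as.integer(runif(15 * 15 * 3) < 0.4), c(15, 15, 3))
  dw <- random_bits(9, 3)
  pw <- random_bits(3, 18)
  bn <- data.frame(gamma = runif(18, 0.5, 1.5), beta = rnorm(18),
                   mu = runif(18, 2, 10), sigma = runif(18, 1, 3))
  res <- dsc_forward(maps, dw, pw, bn)
  expect_identical(dim(res$out), c(13L, 13L, 18L))
  expect_true(all(res$out %in% 0:1))
  # conventional 3D convolution with kernels dw (x) pw, by direct loops
  for (p in c(1, 7, 18)) {
    want <- matrix(0L, 13, 13)
    for (ch in 1:3) {
      kk <- matrix(dw[, ch] * pw[ch, p], 3, 3)
      for (r in 1:13) for (c in 1:13) {
        want[r, c] <- want[r, c] +
          sum(maps[r:(r + 2), c:(c + 2), ch] * kk)
      }
    }
    expect_identical(res$presums[, , p], want)
  }
  # an all-zero pointwise kernel gives a constant output channel
  pw0 <- pw; pw0[, 4] <- 0L
  res0 <- dsc_forward(maps, dw, pw0, bn)
  expect_length(unique(as.vector(res0$out[, , 4])), 1L)
  expect_error(dsc_forward(maps, dw[, 1:2], pw, bn), "channel")
})

test_that("the reference forward pass is a pure, normalized function", {
  w <- random_weights(bdscnn_config(), 13)
  img <- random_image()
  rr <- c(0L, 1L, 0L, 1L)
  f1 <- forward(img, rr, w)
  f2 <- forward(img, rr, w)
  expect_length(f1$scores, 5L)
  expect_equal(sum(f1$scores), 1, tolerance = 1e-9)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$label, names(which.max(f1$fc2_bn)))
  expect_error(forward(random_image(16), rr, w), "32")
  expect_error(forward(img, c(1L, 0L), w), "bits")
})

test_that("parameter accounting reproduces the separable-layer savings", {
  cfg <- bdscnn_config()
  dsc <- count_params_and_ops(cfg, "dsc")
  conv <- count_params_and_ops(cfg, "conventional")
  expect_identical(dsc$per_channel_conventional, 162L)
  expect_identical(dsc$per_channel_dsc, 27L)
  expect_equal(dsc$dsc_param_reduction, 6)
  expect_identical(conv$second_layer_params,
                   dsc$second_layer_params * 6L)
  # operation counts scale with the feature-map area
  cfg2 <- bdscnn_config(M = 24)
  expect_equal(count_params_and_ops(cfg2, "dsc")$coperation,
               cfg2$dsc_side^2 * (3 * 9 + 18 * 3))
})

test_that("training learns a constant class and respects early stopping", {
  rec <- generate_record(80, c(1, 0, 0, 0, 0), rng_seed = 17)
  bs <- segment_beats(rec)
  ds <- build_dataset(bs)
  w <- train_bdscnn(ds, ds, rng_seed = 1, epochs = 60, batch_size = 16,
                    patience = 60)
  ev <- suppressWarnings(evaluate_model(ds, fold_model(w)))
  expect_equal(unname(ev$confusion["N", "N"]), 80)
  expect_equal(sum(ev$pred == "N"), 80)

  # early stopping halts before the epoch cap on unlearnable labels
  set.seed(4)
  noisy <- ds
  noisy$label <- sample(beat_classes(), length(ds$label), replace = TRUE)
  w2 <- train_bdscnn(noisy, noisy, rng_seed = 1, epochs = 60,
                     batch_size = 32, patience = 2)
  expect_lt(max(w2$log$epoch), 60)
})
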