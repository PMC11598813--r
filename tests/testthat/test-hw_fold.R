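test_that("batch-norm folding reproduces the worked comparator example", {
  p <- list(gamma = 0.7093, beta = -2.0248, mu = 0.8035, sigma = 0.9242)
  thr <- fold_bn_threshold(p, eps = 1e-4)
  pre <- attr(thr, "pre_floor")
  # the last printed decimal of the published bound neglects the epsilon
  # stabilizer; with it the bound is 3.44192
  expect_equal(pre, 3.4418, tolerance = 2e-4)
  expect_equal(round(pre, 4), 3.4419)
  expect_identical(as.integer(thr), 3L)
  expect_false(attr(thr, "flipped"))
})

test_that("folding handles identity, shift-only and degenerate parameters", {
  ident <- list(gamma = 1, beta = 0, mu = 0, sigma = 1)
  expect_identical(as.integer(fold_bn_threshold(ident, eps = 1e-12)), 0L)
  shifted <- list(gamma = 2.3, beta = 0, mu = 5, sigma = 1.4)
  expect_identical(as.integer(fold_bn_threshold(shifted)), 5L)
  expect_error(fold_bn_threshold(list(gamma = 0, beta = 1, mu = 0,
                                      sigma = 1)), "gamma")
})

test_that("folded thresholds are exactly equivalent to batch norm + sign", {
  set.seed(3)
  s <- 0:200
  for (draw in 1:500) {
    p <- list(gamma = runif(1, 0.05, 3) * sample(c(-1, 1), 1),
              beta = rnorm(1, 0, 2), mu = runif(1, 0, 150),
              sigma = runif(1, 0.1, 40))
    thr <- fold_bn_threshold(p)
    bn <- p$gamma * (s - p$mu) / sqrt(p$sigma^2 + 1e-4) + p$beta
    fire_ref <- bn > 0
    fire_int <- if (attr(thr, "flipped")) s < thr else s > thr
    expect_identical(fire_int, fire_ref)
  }
})

test_that("the FC2 lookup table covers its sums and preserves order", {
  p <- list(gamma = 1, beta = 0, mu = 0, sigma = 1)
  lut <- build_fc2_lut(p, max_sum = 31, eps = 1e-12)
  expect_length(lut, 32L)
  expect_identical(as.integer(lut), as.integer(round((0:31) * 64)))
  set.seed(8)
  for (draw in 1:50) {
    p <- list(gamma = runif(1, 0.2, 2), beta = rnorm(1),
              mu = runif(1, 0, 30), sigma = runif(1, 1, 6))
    lut <- build_fc2_lut(p, 32)
    expect_true(all(diff(as.integer(lut)) >= 0))  # gamma > 0: nondecreasing
    expect_true(all(diff(attr(lut, "exact")) > 0))
  }
  expect_error(build_fc2_lut(list(gamma = 50, beta = 0, mu = 200, sigma = 0.5),
                             32), "overflows")
  expect_error(build_fc2_lut(p, 0), "max_sum")
})

test_that("integer-only inference matches the reference argmax", {
  cfg <- bdscnn_config()
  for (draw in 1:30) {
    w <- random_weights(cfg, 500 + draw)
    fm <- fold_model(w)
    img <- random_image(32, runif(1, 0.05, 0.6))
    rr <- random_bits(1, 4)[1, ]
    ref <- forward(img, rr, w)
    int <- integer_forward(img, rr, fm)
    expect_identical(int$label, ref$label)
    expect_identical(sum(int$onehot), 1L)
    # strict mode classifies identically (width checks only add warnings)
    strict <- suppressWarnings(integer_forward(img, rr, fm, strict = TRUE))
    expect_identical(strict$label, int$label)
  }
})

test_that("an all-zero image classifies deterministically", {
  w <- random_weights(bdscnn_config(), 77)
  fm <- fold_model(w)
  img <- matrix(0L, 32, 32)
  a <- integer_forward(img, rep(0L, 4), fm)
  b <- integer_forward(img, rep(0L, 4), fm)
  expect_identical(a$label, b$label)
  expect_identical(a$lut_values, b$lut_values)
})

test_that("model bundles round-trip with identical classifications", {
  dir <- withr::local_tempdir()
  cfg <- bdscnn_config()
  w <- random_weights(cfg, 9)
  fm <- fold_model(w)
  write_bundle(w, file.path(dir, "w.json"))
  write_bundle(fm, file.path(dir, "f.json"))
  w2 <- read_bundle(file.path(dir, "w.json"))
  fm2 <- read_bundle(file.path(dir, "f.json"))
  expect_identical(w2$conv1, w$conv1)
  expect_identical(w2$fc1, w$fc1)
  expect_equal(w2$bn_dsc, w$bn_dsc)
  set.seed(55)
  for (i in 1:10) {
    img <- random_image(32, 0.3)
    rr <- random_bits(1, 4)[1, ]
    expect_identical(forward(img, rr, w2)$label, forward(img, rr, w)$label)
    expect_identical(integer_forward(img, rr, fm2)$label,
                     integer_forward(img, rr, fm)$label)
  }
  writeLines('{"format": "other"}', file.path(dir, "bad.json"))
  expect_error(read_bundle(file.path(dir, "bad.json")), "not a bitbeat")
})

test_that("evaluation aggregates predictions with conserved column sums", {
  rec <- generate_record(60, rep(0.2, 5), rng_seed = 31)
  ds <- build_dataset(segment_beats(rec))
  fm <- fold_model(random_weights(bdscnn_config(), 4))
  ev <- suppressWarnings(evaluate_model(ds, fm))
  expect_identical(dim(ev$confusion), c(5L, 5L))
  expect_identical(unname(colSums(ev$confusion)),
                   as.numeric(table(factor(ds$label,
                                           levels = beat_classes()))))
  expect_identical(sum(ev$confusion), 60L)
  empty <- ds
  empty$images <- ds$images[0, , drop = FALSE]
  expect_error(evaluate_model(empty, fm), "empty")
})
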