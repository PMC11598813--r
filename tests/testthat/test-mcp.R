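test_that("merged-kernel geometry follows the size and stride rules", {
  for (KO in 1:4) for (SO in 1:3) for (P in 1:3) for (SP in 1:3) {
    k <- random_bits(KO, KO)
    m <- build_mcpk(k, SO, P, SP)
    expect_identical(nrow(m$bits), as.integer(KO + SO * (P - 1)))
    expect_identical(m$stride, as.integer(SO * SP))
    expect_identical(m$nonzero_count, sum(m$bits))
  }
})

test_that("merging ORs shifted copies of the kernel", {
  expect_true(all(build_mcpk(matrix(1L, 3, 3), 1, 2, 2)$bits == 1L))
  # single center bit lands at the four stride offsets
  k <- matrix(0L, 3, 3); k[2, 2] <- 1L
  m <- build_mcpk(k, 1, 2, 2)
  want <- matrix(0L, 4, 4); want[2:3, 2:3] <- 1L
  expect_identical(m$bits, want)
})

test_that("pruning lists exactly the active positions", {
  z <- build_mcpk(matrix(0L, 3, 3), 1, 2, 2)
  expect_identical(nrow(prune(z)), 0L)
  full <- build_mcpk(matrix(1L, 3, 3), 1, 2, 2)
  expect_identical(nrow(prune(full)), 16L)
  # applying only the pruned positions reproduces mcp_apply
  set.seed(42)
  k <- random_bits(3, 3)
  m <- build_mcpk(k, 1, 2, 2)
  ops <- prune(m)
  img <- random_image(10, 0.3)
  got <- mcp_apply(img, m)
  want <- matrix(0L, nrow(got), ncol(got))
  for (r in seq_len(nrow(got))) for (c in seq_len(ncol(got))) {
    v <- 0L
    for (t in seq_len(nrow(ops))) {
      v <- max(v, img[(r - 1) * m$stride + ops[t, "row"],
                      (c - 1) * m$stride + ops[t, "col"]])
    }
    want[r, c] <- v
  }
  expect_identical(got, want)
})

test_that("single-pass merged kernels equal conv -> binarize -> OR-pool", {
  set.seed(7)
  for (rep in 1:50) {
    img <- random_image(8, runif(1, 0.1, 0.6))
    k <- random_bits(3, 3)
    m <- build_mcpk(k, 1, 2, 2)
    expect_identical(mcp_apply(img, m),
                     or_maxpool(binarize(bconv_valid(img, k)), 2, 2))
  }
  expect_true(all(mcp_apply(matrix(0L, 32, 32),
                            build_mcpk(random_bits(3, 3))) == 0L))
  expect_identical(dim(mcp_apply(random_image(32),
                                 build_mcpk(random_bits(3, 3)))),
                   c(15L, 15L))
  expect_error(mcp_apply(random_image(3), build_mcpk(random_bits(3, 3))),
               "smaller")
})

test_that("adding kernel bits is monotone on the output", {
  set.seed(12)
  for (rep in 1:20) {
    k <- random_bits(3, 3, 0.3)
    zero_at <- which(k == 0L)
    if (length(zero_at) == 0L) next
    k2 <- k; k2[sample(zero_at, 1)] <- 1L
    img <- random_image(12, 0.3)
    a <- mcp_apply(img, build_mcpk(k))
    b <- mcp_apply(img, build_mcpk(k2))
    expect_true(all(b >= a))
  }
})

test_that("operation counting covers merged, pruned and baseline variants", {
  cfg <- bdscnn_config()
  expect_identical(mcp_op_count(cfg, "mcp"), 10800)
  expect_identical(mcp_op_count(cfg, "baseline"), 25650)
  # pruned counts follow the nonzero totals
  k <- random_bits(3, 3)
  m <- build_mcpk(k)
  ms <- list(m, m, m)
  expect_identical(mcp_op_count(cfg, "pruned", ms),
                   15^2 * 3 * m$nonzero_count)
  expect_error(mcp_op_count(cfg, "pruned"), "kernels")
  # degenerate geometry: one output position, one kernel whose merged mask
  # retains a single active bit
  cfg1 <- bdscnn_config(M = 4, K = 1, KD = 1, KP = 1, F1 = 2, rr_bits = 1)
  bits1 <- matrix(0L, 4, 4); bits1[1, 1] <- 1L
  one_bit <- structure(list(bits = bits1, stride = 2L, nonzero_count = 1L),
                       class = "mcp_kernel")
  expect_equal(mcp_op_count(cfg1, "pruned", list(one_bit)), 1)
})

test_that("building a merged kernel after a folded activation is rejected", {
  # the OR-merge identity needs the inter-stage threshold to be exactly 0
  expect_error(build_mcpk(random_bits(3, 3), activation_threshold = 2L),
               "threshold of 0")
  # folding keeps that structure: merged kernels only in the first layer,
  # integer thresholds only after the separable and FC stages
  fm <- fold_model(random_weights(bdscnn_config(), 3))
  expect_length(fm$mcpks, 3L)
  expect_length(fm$pw_fold$threshold, 18L)
})
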