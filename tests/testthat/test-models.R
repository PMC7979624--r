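test_that("parameter counts match a hand-derived per-layer oracle", {
  # unet3d, n_f = 2, depth = 1, 3 input channels, 6 classes, worked layer by
  # layer with conv params = k^3 * c_in * c_out (bias-free) and instance
  # norm params = 2 * c:
  oracle <- sum(
    27 * 3 * 2, 2 * 2,   # encoder level 0, conv1 + norm
    27 * 2 * 2, 2 * 2,   # encoder level 0, conv2 + norm
    27 * 2 * 4, 2 * 4,   # bottleneck conv1 + norm
    27 * 4 * 4, 2 * 4,   # bottleneck conv2 + norm
    1 * 4 * 2, 2 * 2,    # decoder upsample projection (1x1x1) + norm
    27 * 4 * 2, 2 * 2,   # decoder conv1 (after concat) + norm
    27 * 2 * 2, 2 * 2,   # decoder conv2 + norm
    1 * 2 * 6            # classifier (no norm, no bias)
  )
  expect_identical(oracle, 1298)
  m <- build_model(model_config("unet3d", n_f = 2L, depth = 1L),
                   init_weights = FALSE)
  expect_equal(count_parameters(m), oracle)
})

test_that("multires block filter split follows floor(1.95 U / {6,3,2})", {
  expect_identical(bodycomp:::mres_filters(16L), c(5L, 10L, 15L))
  expect_identical(bodycomp:::mres_filters(256L), c(83L, 166L, 249L))
  expect_identical(bodycomp:::mres_filters(1L), c(1L, 1L, 1L))  # floor >= 1
})

test_that("published configurations reproduce the printed parameter counts", {
  printed <- list(unet3d = c(`16` = 5.34, `32` = 21.36, `64` = 85.43),
                  multires_unet3d = c(`32` = 21.24, `64` = 85.10))
  for (fam in names(printed)) for (nf in names(printed[[fam]])) {
    m <- build_model(model_config(fam, n_f = as.integer(nf)),
                     init_weights = FALSE)
    expect_equal(round(count_parameters(m) / 1e6, 2),
                 unname(printed[[fam]][nf]),
                 info = paste(fam, nf))
  }
  # The multires n_f = 16 configuration yields 5.2826 M under the identical
  # block structure that reproduces the n_f = 32 and 64 counts exactly.
  m16 <- build_model(model_config("multires_unet3d", n_f = 16L),
                     init_weights = FALSE)
  expect_equal(round(count_parameters(m16) / 1e6, 2), 5.28)
})

test_that("doubling n_f roughly quadruples the parameter count", {
  for (fam in c("unet3d", "multires_unet3d")) {
    c1 <- count_parameters(build_model(model_config(fam, n_f = 8L),
                                       init_weights = FALSE))
    c2 <- count_parameters(build_model(model_config(fam, n_f = 16L),
                                       init_weights = FALSE))
    expect_gt(c2 / c1, 3.5)
    expect_lt(c2 / c1, 4.5)
  }
})

test_that("count does not depend on weight allocation and all params train", {
  cfg <- micro_model_config()
  a <- build_model(cfg, init_weights = FALSE)
  b <- build_model(cfg, init_weights = TRUE)
  expect_equal(count_parameters(a), count_parameters(b))
  expect_equal(sum(vapply(b$params, length, numeric(1))), count_parameters(b))
})

test_that("network output is a per-voxel probability simplex of input shape", {
  set.seed(9)
  for (fam in c("unet3d", "multires_unet3d")) {
    m <- build_model(model_config(fam, n_f = 2L, depth = 1L,
                                  in_channels = 2L, n_classes = 3L), seed = 4L)
    x <- array(runif(4 * 8 * 6 * 2, -1, 1), c(4, 8, 6, 2))
    p <- bodycomp:::model_forward(m, x)
    expect_equal(dim(p), c(4, 8, 6, 3))
    expect_true(all(p >= 0))
    expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-5)
  }
})

test_that("non-divisible spatial input fails loudly at call time", {
  m <- build_model(micro_model_config(), seed = 1L)
  x <- array(0, c(3, 8, 8, 2))
  expect_error(bodycomp:::model_forward(m, x), "divisible")
})

test_that("weight init is deterministic under seed and checkpoints round-trip", {
  cfg <- micro_model_config()
  m1 <- build_model(cfg, seed = 5L)
  m2 <- build_model(cfg, seed = 5L)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 6L)
  expect_false(identical(m1$params, m3$params))

  p <- file.path(tempfile("ckpt"), "best.ckpt")
  save_checkpoint(m1, p)
  m4 <- load_checkpoint(p)
  expect_identical(m4$params, m1$params)
  expect_equal(m4$config, m1$config)
})
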