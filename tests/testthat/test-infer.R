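test_that("window planning: exact fit, stride 8, end-alignment", {
  cfg <- inference_config()          # 32 slices, 75% overlap
  expect_equal(cfg$stride, 8L)
  expect_equal(plan_windows(32, cfg), 1L)
  expect_equal(plan_windows(40, cfg) - 1L, c(0L, 8L))
  expect_equal(plan_windows(45, cfg) - 1L, c(0L, 8L, 13L))
  # shorter than the window: one padded window
  expect_equal(plan_windows(10, cfg), 1L)
})

test_that("every slice is covered and the last window contains the final slice", {
  cfg <- inference_config()
  for (n in c(32, 33, 40, 45, 64, 100, 129)) {
    starts <- plan_windows(n, cfg)
    covered <- sort(unique(unlist(lapply(starts, function(s) s + 0:31))))
    expect_equal(covered, 1:n, info = paste("n =", n))
    expect_equal(starts[length(starts)] + 31L, n)
  }
})

const_model <- function(p) {
  # prediction function: constant distribution p at every voxel
  function(x) {
    d <- dim(x)
    array(rep(p, each = prod(d[1:3])), c(d[1:3], length(p)))
  }
}

test_that("constant model output is reproduced exactly under any weighting", {
  p <- c(0.1, 0.2, 0.05, 0.3, 0.15, 0.2)
  ct <- tiny_ct(c(20, 8, 8))
  for (wt in c("triangular", "uniform", "gaussian")) {
    cfg <- inference_config(window_slices = 8L, weighting = wt)
    out <- sliding_window_predict(const_model(p), ct,
                                  preprocess_config(), cfg)
    expect_equal(dim(out), c(20, 8, 8, 6))
    for (c in 1:6) expect_equal(max(abs(out[, , , c] - p[c])), 0,
                                tolerance = 1e-12)
  }
})

test_that("a window-sized volume equals a single direct model call", {
  set.seed(31)
  m <- build_model(model_config("unet3d", n_f = 2L, depth = 1L), seed = 8L)
  ph <- generate_phantom(phantom_config(shape = c(8L, 16L, 16L)), seed = 4)
  cfg <- inference_config(window_slices = 8L)
  swp <- sliding_window_predict(m, ph$ct, preprocess_config(), cfg)
  direct <- bodycomp:::predict_window(m, ph$ct$voxels, preprocess_config())
  expect_equal(unclass(swp), direct, tolerance = 1e-12)
})

test_that("overlapping windows blend by the hand-computed weighted average", {
  # two windows of 4 slices over a 6-slice volume (stride 2): window A covers
  # slices 1..4, window B covers 3..6. A z-dependent prediction function
  # lets us verify the per-slice weighted sum by hand.
  cfg <- inference_config(window_slices = 4L, overlap_fraction = 0.5,
                          weighting = "triangular")
  expect_equal(plan_windows(6, cfg), c(1L, 3L))
  w <- bodycomp:::window_weights(cfg)     # 1 2 2 1
  expect_equal(w, c(1, 2, 2, 1))
  calls <- new.env(); calls$n <- 0
  zmodel <- function(x) {
    calls$n <- calls$n + 1
    d <- dim(x)
    p1 <- if (calls$n == 1) 0.9 else 0.3   # class-1 prob per window
    out <- array((1 - p1) / 5, c(d[1:3], 6))
    out[, , , 1] <- p1
    out
  }
  ct <- tiny_ct(c(6, 4, 4))
  out <- sliding_window_predict(zmodel, ct, preprocess_config(), cfg)
  # slices 1-2 only window A; slice 3: A weight 2, B weight 1 ->
  # (2*0.9 + 1*0.3)/3 = 0.7; slice 4: A weight 1, B weight 2 -> 0.5;
  # slices 5-6 only window B.
  expect_equal(out[1, 1, 1, 1], 0.9)
  expect_equal(out[3, 1, 1, 1], 0.7)
  expect_equal(out[4, 1, 1, 1], 0.5)
  expect_equal(out[6, 1, 1, 1], 0.3)
})

test_that("aggregated probabilities stay on the simplex", {
  set.seed(32)
  m <- build_model(model_config("unet3d", n_f = 2L, depth = 1L), seed = 2L)
  ph <- generate_phantom(phantom_config(shape = c(12L, 16L, 16L)), seed = 5)
  out <- sliding_window_predict(m, ph$ct, preprocess_config(),
                                inference_config(window_slices = 8L))
  sums <- apply(unclass(out), 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
})

test_that("ensemble averaging: identity, arithmetic mean, simplex, mismatch", {
  ct <- tiny_ct(c(8, 8, 8))
  cfg <- inference_config(window_slices = 8L)
  pa <- c(0.8, 0.2, 0, 0, 0, 0)
  pb <- c(0.6, 0.4, 0, 0, 0, 0)
  out <- ensemble_predict(list(const_model(pa), const_model(pb)), ct,
                          preprocess_config(), cfg)
  expect_equal(out[1, 1, 1, 1], 0.7)
  expect_equal(out[1, 1, 1, 2], 0.3)
  # ensemble of identical models equals the single model (idempotence)
  out1 <- ensemble_predict(rep(list(const_model(pa)), 5), ct,
                           preprocess_config(), cfg)
  expect_equal(unclass(out1),
               unclass(sliding_window_predict(const_model(pa), ct,
                                              preprocess_config(), cfg)))
  expect_lt(max(abs(apply(unclass(out), 1:3, sum) - 1)), 1e-12)
  # mismatched class counts are rejected
  m3 <- build_model(model_config("unet3d", 2L, 1L, n_classes = 3L),
                    init_weights = FALSE)
  m6 <- build_model(model_config("unet3d", 2L, 1L), init_weights = FALSE)
  expect_error(ensemble_predict(list(m3, m6), ct), "classes")
})

test_that("argmax labelling breaks ties toward the lowest class index", {
  lab <- array(sample(0:5, 3 * 4 * 4, TRUE), c(3, 4, 4))
  oh <- one_hot_field(array(lab, c(3, 4, 4)))
  got <- argmax_labels(structure(oh, class = "prob_field"))
  expect_identical(got$labels, array(as.integer(lab), c(3, 4, 4)))

  p <- array(0, c(1, 1, 1, 6))
  p[1, 1, 1, c(2, 5)] <- 0.5       # exact tie between classes 1 and 4
  expect_identical(argmax_labels(p)$labels[1, 1, 1], 1L)
  u <- array(1 / 6, c(2, 2, 2, 6)) # uniform -> background
  expect_true(all(argmax_labels(u)$labels == 0L))
})
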