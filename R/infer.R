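#' Inference configuration
#'
#' Full volumes are predicted by sliding a window of `window_slices` axial
#' slices along z with `overlap_fraction` overlap (stride =
#' `window_slices * (1 - overlap_fraction)`, 8 slices at the defaults) and
#' aggregating the per-window probabilities with a per-slice weight profile
#' that favours the central slices of each window.
#'
#' @param window_slices slices per window (default 32).
#' @param overlap_fraction fractional overlap between consecutive windows
#'   (default 0.75).
#' @param weighting `"triangular"` (default; `w_z = 1 + min(z, n-1-z)`),
#'   `"uniform"`, or `"gaussian"` (sd = n/4).
#' @return An `inference_config`.
#' @export
inference_config <- function(window_slices = 32L, overlap_fraction = 0.75,
                             weighting = c("triangular", "uniform", "gaussian")) {
  weighting <- match.arg(weighting)
  window_slices <- as.integer(window_slices)
  if (window_slices < 1L) bc_stop("window_slices must be >= 1")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    bc_stop("overlap_fraction must be in [0, 1)")
  stride <- max(1L, as.integer(round(window_slices * (1 - overlap_fraction))))
  structure(list(window_slices = window_slices,
                 overlap_fraction = overlap_fraction,
                 stride = stride, weighting = weighting),
            class = "inference_config")
}

window_weights <- function(config) {
  n <- config$window_slices
  z <- seq_len(n) - 1L
  w <- switch(config$weighting,
              uniform = rep(1, n),
              triangular = 1 + pmin(z, n - 1L - z),
              gaussian = exp(-0.5 * ((z - (n - 1) / 2) / (n / 4))^2))
  if (any(w <= 0)) bc_stop("weights must be strictly positive")
  w
}

#' Plan sliding-window start positions along z
#'
#' Starts at slice 1, 1 + stride, ...; the final window is end-aligned so
#' the last slice is always covered. Volumes shorter than the window yield a
#' single (padded) window starting at 1.
#'
#' @param n_slices number of axial slices.
#' @param config an [inference_config()].
#' @return Integer vector of 1-based start indices.
#' @export
plan_windows <- function(n_slices, config = inference_config()) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) bc_stop("n_slices must be >= 1")
  ws <- config$window_slices
  if (n_slices <= ws) return(1L)
  starts <- seq(1L, n_slices - ws + 1L, by = config$stride)
  last <- n_slices - ws + 1L
  if (starts[length(starts)] != last) starts <- c(starts, last)
  starts
}

# Run the network on one preprocessed window (handles in-plane padding to a
# multiple of downscale * 2^depth via reflect padding).
predict_window <- function(model, hu_window, preprocess) {
  f <- preprocess$downscale_factor
  depth <- if (is.function(model)) 0L else model$config$depth
  m <- f * 2L^depth
  padded <- pad_xy_to_multiple(hu_window, m)
  x <- preprocess_input(padded$grid, preprocess)
  probs <- if (is.function(model)) model(x) else model_forward(model, x)
  # back to native in-plane resolution
  if (f > 1L) {
    d <- dim(probs)
    up <- array(0, c(d[1], d[2] * f, d[3] * f, d[4]))
    for (c in seq_len(d[4]))
      up[, , , c] <- array(.upsample3d_fw(as.numeric(probs[, , , c, drop = FALSE]),
                                          d[1:3], 1L, 1L, f, f),
                           c(d[1], d[2] * f, d[3] * f))
    probs <- up
  }
  if (any(padded$pad > 0L)) {
    d0 <- dim(hu_window)
    probs <- probs[, seq_len(d0[2]), seq_len(d0[3]), , drop = FALSE]
  }
  probs
}

#' Sliding-window prediction of a full CT volume
#'
#' Each z window is preprocessed (HU windows stacked as channels, in-plane
#' downscaled), predicted, upsampled back to the native in-plane grid, and
#' accumulated as `sum(w_z * prob) / sum(w_z)` per voxel. Volumes shorter
#' than the window are padded with air (-1024 HU) and cropped back. The
#' result is a per-voxel probability simplex over the 6 region classes.
#'
#' `model` may also be a function mapping a preprocessed input array
#' `(z, y, x, channels)` to a probability array, which makes the
#' aggregation logic testable with hand-set outputs.
#'
#' @param model a `seg_model` (or a function, see above).
#' @param ct a [ct_volume()].
#' @param preprocess a [preprocess_config()].
#' @param config an [inference_config()].
#' @return 4D array `(z, y, x, class)` of probabilities, class
#'   `prob_field`.
#' @export
sliding_window_predict <- function(model, ct, preprocess = preprocess_config(),
                                   config = inference_config()) {
  stopifnot(inherits(ct, "ct_volume"))
  v <- ct$voxels
  d <- dim(v)
  ws <- config$window_slices
  nz <- d[1]
  pad_z <- max(0L, ws - nz)
  if (pad_z > 0L) {
    v2 <- array(BC_HU_MIN, c(ws, d[2], d[3]))
    v2[seq_len(nz), , ] <- v
    v <- v2
  }
  nz_eff <- dim(v)[1]
  starts <- plan_windows(nz_eff, config)
  w <- window_weights(config)
  n_cls <- if (is.function(model)) NULL else model$config$n_classes
  acc <- NULL
  wsum <- numeric(nz_eff)
  for (s in starts) {
    zi <- s + seq_len(ws) - 1L
    probs <- predict_window(model, v[zi, , , drop = FALSE], preprocess)
    if (is.null(acc)) acc <- array(0, c(nz_eff, dim(probs)[2:4]))
    for (j in seq_len(ws)) {
      acc[zi[j], , , ] <- acc[zi[j], , , ] + w[j] * probs[j, , , ]
      wsum[zi[j]] <- wsum[zi[j]] + w[j]
    }
  }
  acc <- sweep(acc, 1, wsum, "/")
  if (pad_z > 0L) acc <- acc[seq_len(nz), , , , drop = FALSE]
  structure(acc, class = "prob_field")
}

#' Ensemble prediction by probability averaging
#'
#' Predicts with each model (one per cross-validation fold) and averages the
#' probability fields voxel-wise; the mean of simplex vectors is a simplex,
#' so no renormalization is needed.
#'
#' @param models list of `seg_model`s (or prediction functions).
#' @param ct a [ct_volume()].
#' @param preprocess a [preprocess_config()].
#' @param config an [inference_config()].
#' @return A `prob_field` like [sliding_window_predict()].
#' @export
ensemble_predict <- function(models, ct, preprocess = preprocess_config(),
                             config = inference_config()) {
  if (!length(models)) bc_stop("need at least one model")
  ncls <- vapply(models, function(m)
    if (is.function(m)) NA_integer_ else m$config$n_classes, integer(1))
  if (length(unique(ncls[!is.na(ncls)])) > 1)
    bc_stop("models disagree on the number of classes")
  acc <- NULL
  for (m in models) {
    p <- sliding_window_predict(m, ct, preprocess, config)
    acc <- if (is.null(acc)) unclass(p) else acc + unclass(p)
  }
  structure(acc / length(models), class = "prob_field")
}

#' Hard labels from a probability field
#'
#' Per-voxel argmax over classes; exact ties break toward the lowest class
#' index (so an all-uniform field maps to background).
#'
#' @param probs a `prob_field` (4D array `(z, y, x, class)`).
#' @param spacing voxel spacing for the resulting [label_map()].
#' @return A [label_map()] with codes `0..C-1`.
#' @export
argmax_labels <- function(probs, spacing = c(5, 1, 1)) {
  p <- unclass(probs)
  d <- dim(p)
  m <- channel_mat(p)
  best <- rep(0L, nrow(m))
  bestv <- m[, 1]
  for (c in seq_len(d[4])[-1]) {
    better <- m[, c] > bestv          # strict: ties keep the lower index
    best[better] <- c - 1L
    bestv[better] <- m[better, c]
  }
  label_map(array(best, d[1:3]), spacing = spacing)
}
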