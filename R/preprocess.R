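#' HU window specification and preprocessing configuration
#'
#' A HU window `[lo, hi]` maps Hounsfield units linearly to `[0, 1]`,
#' clipping values outside the window. The network input stacks one channel
#' per window and recentres to `[-1, 1]`. The default windows are the full
#' 12-bit scanner range `[-1024, 3071]`, an abdomen window `[-150, 250]`,
#' and a liver window `[-95, 155]`; ablation variants (e.g. a single wide
#' window) are expressed purely through this configuration.
#'
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return `window_spec()` returns a `window_spec`; `preprocess_config()` a
#'   `preprocess_config`.
#' @export
window_spec <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1 || length(hi) != 1 ||
      !is.finite(lo) || !is.finite(hi) || lo >= hi)
    bc_stop("degenerate HU window: need finite lo < hi, got [", lo, ", ", hi, "]")
  structure(list(lo = lo, hi = hi), class = "window_spec")
}

#' @rdname window_spec
#' @param windows list of [window_spec()]s, one input channel each.
#' @param downscale_factor integer >= 1; in-plane (y, x) downscaling factor
#'   applied before the network (the z axis keeps its native slice spacing).
#' @export
preprocess_config <- function(windows = list(window_spec(-1024, 3071),
                                             window_spec(-150, 250),
                                             window_spec(-95, 155)),
                              downscale_factor = 2L) {
  if (inherits(windows, "window_spec")) windows <- list(windows)
  if (!length(windows) || !all(vapply(windows, inherits, TRUE, "window_spec")))
    bc_stop("windows must be a non-empty list of window_spec objects")
  downscale_factor <- as.integer(downscale_factor)
  if (is.na(downscale_factor) || downscale_factor < 1L)
    bc_stop("downscale_factor must be an integer >= 1")
  structure(list(windows = windows, downscale_factor = downscale_factor),
            class = "preprocess_config")
}

#' Normalize HU values into a unit-interval window
#'
#' Maps `v` to `clip((v - lo) / (hi - lo), 0, 1)`; monotone non-decreasing in
#' HU for a fixed window, shape preserving.
#'
#' @param volume a [ct_volume()] or a numeric array of HU values.
#' @param window a [window_spec()].
#' @return Numeric array of the same shape with values in `[0, 1]`.
#' @export
hu_window_normalize <- function(volume, window) {
  stopifnot(inherits(window, "window_spec"))
  v <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  out <- (v - window$lo) / (window$hi - window$lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Stack HU windows as channels centred on zero
#'
#' Each configured window contributes one channel
#' `2 * hu_window_normalize(volume, window) - 1`, so the network input lies
#' in `[-1, 1]`, reaching -1 exactly where HU <= lo and +1 where HU >= hi.
#' Channel order follows the configuration order. No downscaling is applied
#' here; see [downscale_xy()].
#'
#' @inheritParams hu_window_normalize
#' @param config a [preprocess_config()].
#' @return 4D array `(z, y, x, channel)` in `[-1, 1]`.
#' @export
stack_and_center <- function(volume, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  v <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  d <- dim(v)
  out <- array(0, c(d, length(config$windows)))
  for (i in seq_along(config$windows))
    out[, , , i] <- 2 * hu_window_normalize(v, config$windows[[i]]) - 1
  out
}

#' Downscale the in-plane axes of a grid
#'
#' Intensity grids are downscaled by block averaging (factor x factor mean),
#' label grids by nearest-neighbour sampling of the top-left voxel of each
#' block — class codes are never interpolated, and an ignore voxel sampled
#' there propagates. The z extent is unchanged. In-plane dimensions must be
#' divisible by `factor`; pad beforehand otherwise.
#'
#' @param grid 3D numeric array `(z, y, x)`, or a [ct_volume()] /
#'   [label_map()] (spacing is rescaled accordingly).
#' @param factor integer >= 1.
#' @return Downscaled object of the same type.
#' @export
downscale_xy <- function(grid, factor = 2L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) bc_stop("factor must be an integer >= 1")
  if (inherits(grid, "ct_volume")) {
    v <- downscale_xy(grid$voxels, factor)
    return(ct_volume(v, spacing = grid$spacing * c(1, factor, factor),
                     meta = grid$meta))
  }
  if (inherits(grid, "label_map")) {
    l <- downscale_labels_xy(grid$labels, factor)
    return(label_map(l, spacing = grid$spacing * c(1, factor, factor)))
  }
  d <- dim(grid)
  if (length(d) != 3L) bc_stop("grid must be a 3D array (z, y, x)")
  if (factor == 1L) return(grid)
  if (d[2] %% factor != 0L || d[3] %% factor != 0L)
    bc_stop("in-plane dimensions (", d[2], " x ", d[3],
            ") not divisible by factor ", factor)
  out <- .blockmean_xy(as.numeric(grid), dim(grid), factor)
  array(out, c(d[1], d[2] %/% factor, d[3] %/% factor))
}

#' @rdname downscale_xy
#' @param labels integer 3D label array.
#' @export
downscale_labels_xy <- function(labels, factor = 2L) {
  factor <- as.integer(factor)
  d <- dim(labels)
  if (length(d) != 3L) bc_stop("labels must be a 3D array (z, y, x)")
  if (factor == 1L) return(labels)
  if (d[2] %% factor != 0L || d[3] %% factor != 0L)
    bc_stop("in-plane dimensions not divisible by factor ", factor)
  out <- labels[, seq(1, d[2], by = factor), seq(1, d[3], by = factor), drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Network input for a CT (sub)volume
#'
#' Convenience composition used by training and inference: in-plane
#' downscale of the HU grid by block mean, then window stacking and
#' recentring. Returns a `(z, y/f, x/f, n_windows)` array in `[-1, 1]`.
#'
#' @inheritParams stack_and_center
#' @export
preprocess_input <- function(volume, config = preprocess_config()) {
  v <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  v <- downscale_xy(v, config$downscale_factor)
  stack_and_center(v, config)
}

# Reflect-pad the in-plane axes of a 3D array so both are divisible by m.
# Returns list(grid, pad = c(py, px)) with padding appended at the high end.
pad_xy_to_multiple <- function(grid, m) {
  d <- dim(grid)
  py <- (m - d[2] %% m) %% m
  px <- (m - d[3] %% m) %% m
  if (py == 0 && px == 0) return(list(grid = grid, pad = c(0L, 0L)))
  yidx <- c(seq_len(d[2]), if (py > 0) d[2] - seq_len(py) + 1L)
  xidx <- c(seq_len(d[3]), if (px > 0) d[3] - seq_len(px) + 1L)
  list(grid = grid[, yidx, xidx, drop = FALSE], pad = c(py, px))
}
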