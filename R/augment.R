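#' Training-time augmentation configuration
#'
#' Three augmentations are applied, in order: anisotropic in-plane scaling
#' (factors drawn independently for the y and x axes from
#' `U(scale_lo, scale_hi)`, so it also perturbs aspect ratio), random x-axis
#' mirroring with probability 0.5, and random cropping of a
#' `crop_shape` subvolume. Volumes smaller than `crop_shape` are padded
#' (HU at -1024, labels at the ignore code) before cropping.
#'
#' @param scale_lo,scale_hi in-plane scale-factor range (defaults 0.8, 1.2).
#' @param flip_x logical; enable random x mirroring.
#' @param crop_shape integer `(z, y, x)` subvolume size (default
#'   `c(32, 256, 256)`).
#' @return An `augment_config`.
#' @export
augment_config <- function(scale_lo = 0.8, scale_hi = 1.2, flip_x = TRUE,
                           crop_shape = c(32L, 256L, 256L)) {
  if (!(scale_lo > 0 && scale_lo <= scale_hi))
    bc_stop("need 0 < scale_lo <= scale_hi")
  crop_shape <- as.integer(crop_shape)
  if (length(crop_shape) != 3L || any(crop_shape < 1L))
    bc_stop("crop_shape must be three positive integers (z, y, x)")
  structure(list(scale_lo = scale_lo, scale_hi = scale_hi,
                 flip_x = isTRUE(flip_x), crop_shape = crop_shape),
            class = "augment_config")
}

pad_to_shape <- function(arr, shape, fill) {
  d <- dim(arr)
  if (all(d >= shape)) return(arr)
  nd <- pmax(d, shape)
  out <- array(fill, nd)
  lo <- (nd - d) %/% 2L
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- arr
  out
}

#' Random augmentation of a paired CT volume and label map
#'
#' The HU grid is interpolated linearly during scaling; the label grid is
#' sampled nearest-neighbour, so augmented label maps never contain codes
#' absent from the input. Randomness is drawn from R's RNG; with
#' `rng_seed` set the output is a deterministic function of the inputs.
#'
#' @param ct a [ct_volume()].
#' @param labels a [label_map()] with the same grid shape.
#' @param config an [augment_config()].
#' @param rng_seed optional integer; when given, the RNG state is set
#'   locally (and restored afterwards) so the draw is reproducible.
#' @return List with elements `ct` and `labels`, both cropped to
#'   `config$crop_shape`.
#' @export
augment_sample <- function(ct, labels, config = augment_config(),
                           rng_seed = NULL) {
  stopifnot(inherits(ct, "ct_volume"), inherits(labels, "label_map"),
            inherits(config, "augment_config"))
  if (!identical(dim(ct$voxels), dim(labels$labels)))
    bc_stop("CT and label grids differ in shape")
  if (!is.null(rng_seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(rng_seed)
  }
  v <- ct$voxels
  l <- labels$labels
  d <- dim(v)
  # 1) anisotropic in-plane scaling (image linear, labels nearest-neighbour)
  sy <- runif(1, config$scale_lo, config$scale_hi)
  sx <- runif(1, config$scale_lo, config$scale_hi)
  if (sy != 1 || sx != 1) {
    ny <- max(1L, as.integer(round(d[2] * sy)))
    nx <- max(1L, as.integer(round(d[3] * sx)))
    v <- array(.resize_xy(as.numeric(v), d, ny, nx, 0L), c(d[1], ny, nx))
    l <- array(as.integer(.resize_xy(as.numeric(l), d, ny, nx, 1L)), c(d[1], ny, nx))
  }
  # 2) x-axis mirroring with probability 0.5
  if (config$flip_x && runif(1) < 0.5) {
    v <- v[, , rev(seq_len(dim(v)[3])), drop = FALSE]
    l <- l[, , rev(seq_len(dim(l)[3])), drop = FALSE]
  }
  # 3) pad (HU -1024 / ignore) then random crop
  cs <- config$crop_shape
  v <- pad_to_shape(v, cs, fill = BC_HU_MIN)
  l <- pad_to_shape(l, cs, fill = BC_IGNORE)
  d2 <- dim(v)
  start <- vapply(1:3, function(a) {
    if (d2[a] == cs[a]) 1L else as.integer(sample.int(d2[a] - cs[a] + 1L, 1L))
  }, integer(1))
  zi <- start[1] + seq_len(cs[1]) - 1L
  yi <- start[2] + seq_len(cs[2]) - 1L
  xi <- start[3] + seq_len(cs[3]) - 1L
  list(ct = ct_volume(v[zi, yi, xi, drop = FALSE], spacing = ct$spacing,
                      meta = ct$meta),
       labels = label_map(l[zi, yi, xi, drop = FALSE], spacing = labels$spacing))
}
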