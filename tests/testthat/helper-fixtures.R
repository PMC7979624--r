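# Shared fixtures: tiny volumes and configurations used across test files.

tiny_ct <- function(shape = c(8, 12, 12), value = 0, spacing = c(5, 1, 1)) {
  ct_volume(array(value, shape), spacing = spacing)
}

tiny_phantom_config <- function() {
  phantom_config(shape = c(10L, 32L, 32L), spacing = c(5, 2, 2))
}

micro_model_config <- function() {
  model_config("unet3d", n_f = 2L, depth = 1L, in_channels = 2L, n_classes = 3L)
}

# A one-hot probability field matching an integer label array (ignore voxels
# get a uniform distribution; they must not matter).
one_hot_field <- function(labels, n_classes = 6L) {
  d <- dim(labels)
  p <- array(0, c(d, n_classes))
  m <- matrix(1 / n_classes, prod(d), n_classes)
  keep <- as.integer(labels) != 255L
  m[keep, ] <- 0
  m[cbind(which(keep), as.integer(labels)[keep] + 1L)] <- 1
  array(m, c(d, n_classes))
}
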