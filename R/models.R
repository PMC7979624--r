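#' Segmentation network configuration
#'
#' Two architecture families are provided: a plain 3D U-Net (`"unet3d"`) and
#' a multi-resolution 3D U-Net (`"multires_unet3d"`). Both use bias-free
#' convolutions, each followed by instance normalization (learned scale and
#' shift per channel) and ReLU; 2x2x2 max pooling between encoder levels;
#' and trilinear upsampling followed by a 1x1x1 projection convolution
#' halving the channel count in the decoder. With `depth` pooling stages the
#' feature-map width at level `d` is `n_f * 2^d`, so with depth 4 and
#' n_f = 16/32/64 the bottleneck carries 256/512/1024 features.
#'
#' The published trainable-parameter counts for the six (family, n_f)
#' configurations pin the block micro-structure down; the reconstruction
#' that reproduces them is documented in the package vignette. The
#' multi-resolution blocks use width `W = 1.95 * U` split into three chained
#' 3x3x3 convolutions of `floor(W/6)`, `floor(W/3)` and `floor(W/2)`
#' filters with a 1x1x1 shortcut, and residual ("res path") skip blocks of
#' decreasing length with a 3x3x3 convolution plus 1x1x1 shortcut per stage.
#'
#' @param family `"unet3d"` or `"multires_unet3d"`.
#' @param n_f initial feature-map count (the paper evaluates 16, 32, 64).
#' @param depth number of pooling stages (default 4).
#' @param in_channels input channels, one per HU window (default 3).
#' @param n_classes output classes (default 6).
#' @return A `model_config`.
#' @export
model_config <- function(family = c("multires_unet3d", "unet3d"),
                         n_f = 16L, depth = 4L, in_channels = 3L,
                         n_classes = 6L) {
  family <- match.arg(family)
  n_f <- as.integer(n_f); depth <- as.integer(depth)
  if (n_f < 1L || depth < 1L) bc_stop("n_f and depth must be positive integers")
  structure(list(family = family, n_f = n_f, depth = depth,
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes)),
            class = "model_config")
}

# Multi-resolution block filter split. Width W = alpha * U is divided over
# three chained convolutions roughly as W/6, W/3, W/2 (floored, min 1).
mres_filters <- function(U, alpha = 1.95) {
  W <- alpha * U
  pmax(1L, as.integer(floor(W * c(1 / 6, 1 / 3, 1 / 2))))
}

build_unet3d_graph <- function(cfg) {
  nb <- nn_builder()
  nf <- cfg$n_f
  ch <- function(d) nf * 2L^d
  x <- nb_input(nb, cfg$in_channels)
  skips <- integer(cfg$depth)
  skip_ch <- integer(cfg$depth)
  cur <- x; cur_ch <- cfg$in_channels
  for (d in 0:cfg$depth) {
    nm <- paste0("enc", d)
    cur <- nb_conv(nb, cur, 3L, cur_ch, ch(d), paste0(nm, ".conv1"))
    cur <- nb_conv(nb, cur, 3L, ch(d), ch(d), paste0(nm, ".conv2"))
    cur_ch <- ch(d)
    if (d < cfg$depth) {
      skips[d + 1] <- cur
      skip_ch[d + 1] <- cur_ch
      cur <- nb_pool(nb, cur, cur_ch)
    }
  }
  for (d in (cfg$depth - 1):0) {
    nm <- paste0("dec", d)
    cur <- nb_upsample(nb, cur, cur_ch)
    cur <- nb_conv(nb, cur, 1L, cur_ch, ch(d), paste0(nm, ".proj"))
    cur <- nb_concat(nb, cur, skips[d + 1], ch(d), skip_ch[d + 1])
    cur <- nb_conv(nb, cur, 3L, 2L * ch(d), ch(d), paste0(nm, ".conv1"))
    cur <- nb_conv(nb, cur, 3L, ch(d), ch(d), paste0(nm, ".conv2"))
    cur_ch <- ch(d)
  }
  cur <- nb_conv(nb, cur, 1L, cur_ch, cfg$n_classes, "classifier",
                 norm = FALSE, act = FALSE)
  out <- nb_softmax(nb, cur, cfg$n_classes)
  list(nb = nb, out_id = out)
}

# One multi-resolution block: three chained 3x3x3 convolutions whose outputs
# are concatenated, plus a 1x1x1 shortcut over the whole block.
nb_mres_block <- function(nb, input, in_ch, U, name) {
  f <- mres_filters(U)
  c1 <- nb_conv(nb, input, 3L, in_ch, f[1], paste0(name, ".conv1"))
  c2 <- nb_conv(nb, c1, 3L, f[1], f[2], paste0(name, ".conv2"))
  c3 <- nb_conv(nb, c2, 3L, f[2], f[3], paste0(name, ".conv3"))
  cc <- nb_concat(nb, c1, c2, f[1], f[2])
  cc <- nb_concat(nb, cc, c3, f[1] + f[2], f[3])
  out_ch <- sum(f)
  sc <- nb_conv(nb, input, 1L, in_ch, out_ch, paste0(name, ".shortcut"), act = FALSE)
  list(id = nb_add(nb, cc, sc, out_ch), ch = out_ch)
}

# Residual path: `length` stages of 3x3x3 convolution with 1x1x1 shortcut.
nb_res_path <- function(nb, input, in_ch, filters, length, name) {
  cur <- input; cur_ch <- in_ch
  for (s in seq_len(length)) {
    nm <- paste0(name, ".stage", s)
    cv <- nb_conv(nb, cur, 3L, cur_ch, filters, paste0(nm, ".conv"))
    sc <- nb_conv(nb, cur, 1L, cur_ch, filters, paste0(nm, ".shortcut"), act = FALSE)
    cur <- nb_add(nb, cv, sc, filters)
    cur_ch <- filters
  }
  list(id = cur, ch = cur_ch)
}

build_multires_graph <- function(cfg) {
  nb <- nn_builder()
  nf <- cfg$n_f
  U <- function(d) nf * 2L^d
  x <- nb_input(nb, cfg$in_channels)
  skips <- integer(cfg$depth); skip_ch <- integer(cfg$depth)
  cur <- x; cur_ch <- cfg$in_channels
  for (d in 0:cfg$depth) {
    blk <- nb_mres_block(nb, cur, cur_ch, U(d), paste0("enc", d))
    cur <- blk$id; cur_ch <- blk$ch
    if (d < cfg$depth) {
      rp <- nb_res_path(nb, cur, cur_ch, U(d), cfg$depth - d, paste0("respath", d))
      skips[d + 1] <- rp$id; skip_ch[d + 1] <- rp$ch
      cur <- nb_pool(nb, cur, cur_ch)
    }
  }
  for (d in (cfg$depth - 1):0) {
    nm <- paste0("dec", d)
    cur <- nb_upsample(nb, cur, cur_ch)
    cur <- nb_conv(nb, cur, 1L, cur_ch, U(d), paste0(nm, ".proj"))
    cur <- nb_concat(nb, cur, skips[d + 1], U(d), skip_ch[d + 1])
    blk <- nb_mres_block(nb, cur, U(d) + skip_ch[d + 1], U(d), nm)
    cur <- blk$id; cur_ch <- blk$ch
  }
  cur <- nb_conv(nb, cur, 1L, cur_ch, cfg$n_classes, "classifier",
                 norm = FALSE, act = FALSE)
  out <- nb_softmax(nb, cur, cfg$n_classes)
  list(nb = nb, out_id = out)
}

#' Build a segmentation model
#'
#' Constructs the network graph for a [model_config()] and (optionally)
#' initializes its weights (He initialization, deterministic under `seed`).
#' With `init_weights = FALSE` only parameter shapes are stored, which is
#' enough for [count_parameters()] and topology inspection of the largest
#' configurations without allocating hundreds of MB of weights.
#'
#' @param config a [model_config()].
#' @param init_weights allocate and initialize weights (default TRUE).
#' @param seed integer seed for weight initialization.
#' @return A `seg_model`.
#' @examples
#' m <- build_model(model_config("unet3d", n_f = 16), init_weights = FALSE)
#' count_parameters(m) / 1e6   # 5.34 M
#' @export
build_model <- function(config, init_weights = TRUE, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  g <- switch(config$family,
              unet3d = build_unet3d_graph(config),
              multires_unet3d = build_multires_graph(config))
  model <- structure(list(config = config,
                          nodes = g$nb$nodes,
                          param_shapes = g$nb$param_shapes,
                          params = NULL,
                          out_id = g$out_id,
                          init_seed = as.integer(seed)),
                     class = "seg_model")
  if (init_weights) model$params <- nn_init_params(model$param_shapes, seed)
  model
}

#' Count trainable parameters of a model
#'
#' Sums the sizes of all trainable containers (convolution weights and
#' instance-norm scale/shift vectors). All parameters are trainable in this
#' design, so the count does not depend on whether weights are allocated.
#'
#' @param model a `seg_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "seg_model"))
  sum(vapply(model$param_shapes, prod, numeric(1)))
}

#' @export
print.seg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<seg_model> %s, n_f = %d, depth = %d, %d -> %d channels\n",
              cfg$family, cfg$n_f, cfg$depth, cfg$in_channels, cfg$n_classes))
  cat(sprintf("  trainable parameters: %s (%.2f M)%s\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6,
              if (is.null(x$params)) " [weights not allocated]" else ""))
  invisible(x)
}

#' @export
summary.seg_model <- function(object, ...) {
  print(object)
  ops <- table(vapply(object$nodes, `[[`, character(1), "op"))
  cat("  graph:", paste(sprintf("%s x%d", names(ops), as.integer(ops)),
                        collapse = ", "), "\n")
  invisible(object)
}

# Raw window-level forward pass: (z, y, x, C_in) in [-1, 1] ->
# per-voxel class probabilities (z, y, x, n_classes).
model_forward <- function(model, x) {
  d <- dim(x)
  m <- 2L^model$config$depth
  if (any(d[1:3] %% m != 0L))
    bc_stop("input spatial dims (", paste(d[1:3], collapse = "x"),
            ") must be divisible by 2^depth = ", m)
  nn_forward(model, x, train = FALSE)$out
}

#' Predict class probabilities for a CT volume
#'
#' Full-volume prediction through the sliding-window machinery (see
#' [sliding_window_predict()]).
#'
#' @param object a `seg_model` with initialized weights.
#' @param ct a [ct_volume()].
#' @param preprocess a [preprocess_config()].
#' @param inference an [inference_config()].
#' @param ... unused.
#' @return A probability field; see [sliding_window_predict()].
#' @export
predict.seg_model <- function(object, ct, preprocess = preprocess_config(),
                              inference = inference_config(), ...) {
  sliding_window_predict(object, ct, preprocess, inference)
}

# (De)serialization of model weights: a plain RDS of config + params.
#' Save or load model weights
#'
#' @param model a `seg_model`.
#' @param path file path (conventionally `fold<k>/best.ckpt`).
#' @return `load_checkpoint()` returns a `seg_model`.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(config = model$config, params = model$params,
               init_seed = model$init_seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$config, init_weights = FALSE)
  model$params <- obj$params
  model$init_seed <- obj$init_seed
  model
}
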