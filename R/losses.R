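#' Supervision loss configuration
#'
#' The training loss is the equally weighted sum of a softmax cross-entropy
#' term and a generalized Soerensen Dice term computed over the foreground
#' classes only (the background class is deliberately excluded from the Dice
#' term to upweight the foreground). Voxels carrying the ignore label
#' contribute to neither term.
#'
#' @param epsilon smoothing constant in the Dice ratio (default 1e-5: small
#'   enough not to bias scores on regions of thousands of voxels, large
#'   enough to stabilize classes absent from a crop).
#' @param w_xce,w_dice loss weights (defaults 0.5/0.5, must sum to 1).
#' @param background_index class index (0-based code) excluded from the Dice
#'   term.
#' @return A `loss_config`.
#' @export
loss_config <- function(epsilon = 1e-5, w_xce = 0.5, w_dice = 0.5,
                        background_index = 0L) {
  if (epsilon <= 0) bc_stop("epsilon must be > 0")
  if (abs(w_xce + w_dice - 1) > 1e-12) bc_stop("loss weights must sum to 1")
  structure(list(epsilon = epsilon, w_xce = w_xce, w_dice = w_dice,
                 background_index = as.integer(background_index)),
            class = "loss_config")
}

# Internal: flatten a probability field and label grid to an (N x C)
# probability matrix, a class-index vector (1-based), and the keep mask.
flatten_supervision <- function(probs, labels) {
  l <- if (inherits(labels, "label_map")) labels$labels else labels
  d <- dim(probs)
  if (!identical(as.integer(d[1:3]), as.integer(dim(l))))
    bc_stop("probability field and label grid differ in shape")
  C <- d[4]
  pm <- channel_mat(probs)
  lv <- as.integer(l)
  keep <- lv != BC_IGNORE
  list(pm = pm, lv = lv, keep = keep, C = C)
}

#' Softmax cross-entropy loss with ignore labels
#'
#' `-(1/N) * sum_n sum_c y_cn * log(yhat_cn)` where N counts only
#' non-ignored voxels. If every voxel is ignored the loss is defined as 0
#' (with a warning), matching the convention that unannotated blocks carry
#' no supervision signal.
#'
#' @param probs 4D array `(z, y, x, class)` of per-voxel class
#'   probabilities.
#' @param labels [label_map()] or integer array with codes 0..C-1 and 255 =
#'   ignore.
#' @return Scalar loss.
#' @export
xce_loss <- function(probs, labels) {
  f <- flatten_supervision(probs, labels)
  n <- sum(f$keep)
  if (n == 0L) {
    warning("all voxels ignored; cross-entropy defined as 0")
    return(0)
  }
  idx <- cbind(which(f$keep), f$lv[f$keep] + 1L)
  p <- pmax(f$pm[idx], 1e-12)
  -sum(log(p)) / n
}

#' Generalized Dice loss over foreground classes with ignore labels
#'
#' `1 - (1/(C-1)) * sum_fg (2 * sum_n yhat*y + eps) / (sum_n yhat + y + eps)`
#' with sums over non-ignored voxels only and the background class excluded.
#' A foreground class absent from both the prediction mass and the ground
#' truth contributes a ratio of eps/eps = 1, i.e. no penalty.
#'
#' @inheritParams xce_loss
#' @param config a [loss_config()].
#' @return Scalar loss in `[0, 1]`.
#' @export
generalized_dice_loss <- function(probs, labels, config = loss_config()) {
  f <- flatten_supervision(probs, labels)
  keep <- f$keep
  fg <- setdiff(seq_len(f$C) - 1L, config$background_index)
  total <- 0
  for (c in fg) {
    y <- as.numeric(f$lv[keep] == c)
    p <- f$pm[keep, c + 1L]
    total <- total + (2 * sum(p * y) + config$epsilon) /
      (sum(p) + sum(y) + config$epsilon)
  }
  1 - total / length(fg)
}

#' Combined supervision loss
#'
#' `w_xce * L_XCE + w_dice * L_Dice` (defaults 0.5/0.5).
#'
#' @inheritParams generalized_dice_loss
#' @return Scalar loss.
#' @export
combined_loss <- function(probs, labels, config = loss_config()) {
  config$w_xce * xce_loss(probs, labels) +
    config$w_dice * generalized_dice_loss(probs, labels, config)
}

# Gradient of the combined loss w.r.t. the probability field. Ignored
# voxels receive exactly zero gradient. Returns a 4D array like probs.
combined_loss_grad <- function(probs, labels, config = loss_config()) {
  f <- flatten_supervision(probs, labels)
  keep <- f$keep
  n <- sum(keep)
  g <- matrix(0, nrow(f$pm), f$C)
  if (n > 0L) {
    # XCE: dL/dp_{c,n} = -y_{c,n} / (p_{c,n} * N)
    idx <- cbind(which(keep), f$lv[keep] + 1L)
    g[idx] <- -config$w_xce / (pmax(f$pm[idx], 1e-12) * n)
    # Dice: per foreground class c, T = (2*sum(py)+eps)/(sum(p)+sum(y)+eps);
    # dT/dp_n = (2*y_n*D - Nm) / D^2; dL/dp = -w_dice/(C-1) * dT/dp.
    fg <- setdiff(seq_len(f$C) - 1L, config$background_index)
    for (c in fg) {
      y <- as.numeric(f$lv[keep] == c)
      p <- f$pm[keep, c + 1L]
      Nm <- 2 * sum(p * y) + config$epsilon
      D <- sum(p) + sum(y) + config$epsilon
      g[keep, c + 1L] <- g[keep, c + 1L] -
        config$w_dice / length(fg) * (2 * y * D - Nm) / (D * D)
    }
  }
  array(g, dim(probs))
}

#' Soerensen Dice score between two label maps for one class
#'
#' `2|P & T| / (|P| + |T|)` over non-ignored voxels (a voxel is excluded if
#' it is ignored in either map). Defined as 1 when both masks are empty.
#'
#' @param pred,truth [label_map()]s or integer arrays of equal shape.
#' @param class_code region code in 0..5.
#' @return Scalar in `[0, 1]`.
#' @export
dice_score <- function(pred, truth, class_code) {
  p <- if (inherits(pred, "label_map")) pred$labels else pred
  t <- if (inherits(truth, "label_map")) truth$labels else truth
  if (!identical(dim(p), dim(t))) bc_stop("label grids differ in shape")
  class_code <- as.integer(class_code)
  if (!class_code %in% BC_CODES)
    bc_stop("unknown class code ", class_code)
  keep <- p != BC_IGNORE & t != BC_IGNORE
  pi <- p[keep] == class_code
  ti <- t[keep] == class_code
  denom <- sum(pi) + sum(ti)
  if (denom == 0L) return(1)
  2 * sum(pi & ti) / denom
}

#' Mean foreground Dice score
#'
#' Macro average of [dice_score()] over the five foreground region codes.
#'
#' @inheritParams dice_score
#' @param class_codes codes to average over (default foreground 1..5).
#' @return Scalar in `[0, 1]`.
#' @export
mean_dice <- function(pred, truth, class_codes = 1:5) {
  mean(vapply(class_codes, function(cc) dice_score(pred, truth, cc), numeric(1)))
}

#' Intra-class correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' between two measurement series (e.g. per-slice tissue volumes from the
#' automated pipeline and from ground-truth annotations). Computed from the
#' two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with k = 2 raters.
#'
#' @param series_a,series_b numeric vectors of equal length >= 3.
#' @return Scalar ICC.
#' @export
icc <- function(series_a, series_b) {
  a <- as.numeric(series_a); b <- as.numeric(series_b)
  if (length(a) != length(b)) bc_stop("series lengths differ")
  n <- length(a)
  if (n < 3L) bc_stop("need at least 3 paired measurements for the ICC")
  x <- cbind(a, b)
  if (var(a) == 0 && var(b) == 0)
    bc_stop("ICC undefined: zero variance in both series")
  k <- 2
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  grand <- mean(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Bland-Altman agreement statistics
#'
#' Mean difference (bias) and 95% limits of agreement
#' (`bias +/- 1.96 * sd(diff)`) between two measurement series.
#'
#' @inheritParams icc
#' @return List with `bias`, `loa_lo`, `loa_hi`, `sd_diff`, and the paired
#'   `means`/`diffs` used for plotting.
#' @export
bland_altman <- function(series_a, series_b) {
  a <- as.numeric(series_a); b <- as.numeric(series_b)
  if (length(a) != length(b)) bc_stop("series lengths differ")
  d <- a - b
  m <- (a + b) / 2
  s <- sd(d)
  list(bias = mean(d), sd_diff = s,
       loa_lo = mean(d) - 1.96 * s, loa_hi = mean(d) + 1.96 * s,
       means = m, diffs = d)
}
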