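#' Optimizer configuration (AdamW with stepped exponential LR decay)
#'
#' Adam with decoupled weight decay; the learning rate starts at `lr0` and
#' is multiplied by `lr_gamma` every `lr_step` epochs
#' (`lr0 * lr_gamma^floor(epoch / lr_step)`). Defaults follow the
#' segmentation training recipe: beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
#' weight decay 1e-4, lr0 = 1e-4, gamma 0.95 every 50 epochs.
#'
#' @param beta1,beta2,eps Adam moment parameters.
#' @param weight_decay decoupled weight decay coefficient.
#' @param lr0 initial learning rate.
#' @param lr_gamma,lr_step decay factor and step length (epochs).
#' @param epochs total training epochs.
#' @param seed integer seed controlling initialization and augmentation.
#' @return An `optimizer_config`.
#' @export
optimizer_config <- function(beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
                             weight_decay = 1e-4, lr0 = 1e-4,
                             lr_gamma = 0.95, lr_step = 50L,
                             epochs = 100L, seed = 1L) {
  vals <- c(beta1, beta2, eps, weight_decay, lr0, lr_gamma, lr_step, epochs)
  if (any(!is.finite(vals)) || any(vals[c(3, 4, 5, 6, 7)] <= 0))
    bc_stop("optimizer parameters must be positive and finite")
  structure(list(beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay, lr0 = lr0, lr_gamma = lr_gamma,
                 lr_step = as.integer(lr_step), epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Learning rate at a given epoch
#'
#' Closed form `lr0 * lr_gamma^floor(epoch / lr_step)` (epoch 0-based).
#'
#' @param epoch epoch index >= 0.
#' @param config an [optimizer_config()].
#' @return Learning rate.
#' @export
lr_at_epoch <- function(epoch, config = optimizer_config()) {
  if (any(epoch < 0)) bc_stop("epoch must be >= 0")
  config$lr0 * config$lr_gamma^floor(epoch / config$lr_step)
}

#' Cross-validation fold assignment
#'
#' Deterministic under `seed`; the shuffled ids are dealt round-robin into
#' `k` folds, so fold sizes differ by at most one (40 ids under 5 folds give
#' five validation folds of 8, i.e. 32 training / 8 validation volumes per
#' run).
#'
#' @param ids vector of volume identifiers.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `cv_plan`: list with `k` and `assignments` (named integer
#'   vector mapping id -> fold in 1..k).
#' @export
make_cv_splits <- function(ids, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) bc_stop("k must be >= 2")
  if (length(ids) < k) bc_stop("fewer ids (", length(ids), ") than folds (", k, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  perm <- sample(seq_along(ids))
  fold <- integer(length(ids))
  fold[perm] <- rep_len(seq_len(k), length(ids))
  structure(list(k = k, assignments = setNames(fold, as.character(ids))),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d folds, %d ids (fold sizes: %s)\n", x$k,
              length(x$assignments),
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}

# One training step on a single (ct, sparse labels) sample. Returns the loss.
train_step <- function(model, state, ct, labels, aug_cfg, pre_cfg, loss_cfg,
                       lr, opt_cfg) {
  s <- augment_sample(ct, labels, aug_cfg)
  x <- preprocess_input(s$ct, pre_cfg)
  lab <- downscale_labels_xy(s$labels$labels, pre_cfg$downscale_factor)
  fw <- nn_forward(model, x, train = TRUE)
  loss <- combined_loss(fw$out, lab, loss_cfg)
  g <- combined_loss_grad(fw$out, lab, loss_cfg)
  grads <- nn_backward(model, fw, g)
  upd <- adamw_step(model$params, grads, state, lr = lr,
                    beta1 = opt_cfg$beta1, beta2 = opt_cfg$beta2,
                    eps = opt_cfg$eps, weight_decay = opt_cfg$weight_decay)
  model$params <- upd$params
  list(model = model, state = upd$state, loss = loss)
}

# Mean foreground Dice of a model over a list of samples (full-volume
# sliding-window prediction against the sparse ground truth, i.e. annotated
# slices only).
validate_dice <- function(model, samples, pre_cfg, inf_cfg) {
  scores <- vapply(samples, function(s) {
    probs <- sliding_window_predict(model, s$ct, pre_cfg, inf_cfg)
    pred <- argmax_labels(probs, spacing = s$ct$spacing)
    mean_dice(pred$labels, s$sparse$labels)
  }, numeric(1))
  mean(scores)
}

#' Train one cross-validation fold
#'
#' Batch size is one subvolume; an epoch draws one random augmented crop
#' from every training volume. Validation (full-volume sliding-window
#' prediction, mean foreground Dice on annotated slices) runs every
#' `val_every` epochs and at the end; the returned model carries the
#' weights of the best validation epoch.
#'
#' @param train_samples,val_samples lists of samples, each a list with
#'   elements `ct` ([ct_volume()]) and `sparse` ([label_map()]).
#' @param model_cfg a [model_config()].
#' @param opt_cfg an [optimizer_config()] (`epochs`, `seed` included).
#' @param loss_cfg a [loss_config()].
#' @param aug_cfg an [augment_config()].
#' @param pre_cfg a [preprocess_config()].
#' @param inf_cfg an [inference_config()] used for validation.
#' @param val_every validate every k epochs (default 10).
#' @param verbose print per-validation progress.
#' @param retry_below convergence safeguard: if the best validation Dice of
#'   the finished run is below this value, the fold is considered a failed
#'   run (a local optimum in which a rare class — typically the thoracic
#'   cavity — never emerges; outcomes are strongly bimodal) and training
#'   restarts once from a reseeded initialization, keeping the better of
#'   the two runs. `0` disables the safeguard.
#' @return A `seg_fit`: list with `model` (best weights), `log` (data.frame
#'   epoch/loss/val_dice), `best_epoch`, `best_dice`, `restarted`.
#' @export
train_fold <- function(train_samples, val_samples, model_cfg,
                       opt_cfg = optimizer_config(),
                       loss_cfg = loss_config(),
                       aug_cfg = augment_config(),
                       pre_cfg = preprocess_config(),
                       inf_cfg = inference_config(),
                       val_every = 10L, verbose = FALSE,
                       retry_below = 0) {
  fit <- train_fold_once(train_samples, val_samples, model_cfg, opt_cfg,
                         loss_cfg, aug_cfg, pre_cfg, inf_cfg, val_every,
                         verbose)
  fit$restarted <- FALSE
  if (retry_below > 0 && opt_cfg$epochs > 0L &&
      is.finite(fit$best_dice) && fit$best_dice < retry_below) {
    if (verbose)
      message(sprintf("fold failed to converge (best Dice %.3f < %.2f); restarting once",
                      fit$best_dice, retry_below))
    opt2 <- opt_cfg
    opt2$seed <- opt_cfg$seed + 100L
    fit2 <- train_fold_once(train_samples, val_samples, model_cfg, opt2,
                            loss_cfg, aug_cfg, pre_cfg, inf_cfg, val_every,
                            verbose)
    if (fit2$best_dice > fit$best_dice) {
      fit2$restarted <- TRUE
      return(fit2)
    }
    fit$restarted <- TRUE
  }
  fit
}

train_fold_once <- function(train_samples, val_samples, model_cfg,
                            opt_cfg, loss_cfg, aug_cfg, pre_cfg, inf_cfg,
                            val_every, verbose) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(opt_cfg$seed)
  model <- build_model(model_cfg, init_weights = TRUE, seed = opt_cfg$seed)
  state <- adamw_state(model$params)
  log <- data.frame(epoch = integer(), loss = numeric(), val_dice = numeric())
  best <- list(params = model$params, dice = -Inf, epoch = 0L)
  if (opt_cfg$epochs == 0L)
    return(structure(list(model = model, log = log, best_epoch = 0L,
                          best_dice = NA_real_),
                     class = "seg_fit"))
  for (epoch in seq_len(opt_cfg$epochs)) {
    lr <- lr_at_epoch(epoch - 1L, opt_cfg)
    losses <- numeric(length(train_samples))
    for (i in sample(seq_along(train_samples))) {
      st <- train_step(model, state, train_samples[[i]]$ct,
                       train_samples[[i]]$sparse, aug_cfg, pre_cfg, loss_cfg,
                       lr, opt_cfg)
      model <- st$model; state <- st$state; losses[i] <- st$loss
    }
    vd <- NA_real_
    if (epoch %% val_every == 0L || epoch == opt_cfg$epochs) {
      vd <- validate_dice(model, val_samples, pre_cfg, inf_cfg)
      if (is.na(vd)) bc_stop("validation Dice is NaN at epoch ", epoch)
      if (vd > best$dice) best <- list(params = model$params, dice = vd,
                                       epoch = epoch)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val dice %.4f", epoch,
                        mean(losses), vd))
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = mean(losses),
                                 val_dice = vd))
  }
  model$params <- best$params
  structure(list(model = model, log = log, best_epoch = best$epoch,
                 best_dice = best$dice),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  cat(sprintf("<seg_fit> %s, best validation mean foreground Dice %.4f at epoch %d/%d\n",
              x$model$config$family, x$best_dice, x$best_epoch,
              max(x$log$epoch, 0L)))
  invisible(x)
}

#' Cross-validated training of all folds
#'
#' Splits `samples` with [make_cv_splits()], trains one model per fold and
#' returns them (the fold ensemble used by [ensemble_predict()]).
#'
#' @param samples named list of samples (see [train_fold()]).
#' @param k number of folds.
#' @param checkpoint_dir optional directory; fold f's best weights are
#'   written to `fold<f>/best.ckpt`.
#' @inheritParams train_fold
#' @return A `seg_cv`: list with `fits` (per fold), `plan`, and
#'   `models` (convenience list of best models).
#' @export
train_seg_cv <- function(samples, k = 5L, model_cfg,
                         opt_cfg = optimizer_config(),
                         loss_cfg = loss_config(),
                         aug_cfg = augment_config(),
                         pre_cfg = preprocess_config(),
                         inf_cfg = inference_config(),
                         val_every = 10L, checkpoint_dir = NULL,
                         verbose = FALSE, retry_below = 0) {
  ids <- names(samples)
  if (is.null(ids)) ids <- as.character(seq_along(samples))
  plan <- make_cv_splits(ids, k = k, seed = opt_cfg$seed)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    val_ids <- ids[plan$assignments == f]
    tr_ids <- setdiff(ids, val_ids)
    fold_opt <- opt_cfg
    fold_opt$seed <- opt_cfg$seed + f
    fits[[f]] <- train_fold(samples[tr_ids], samples[val_ids], model_cfg,
                            fold_opt, loss_cfg, aug_cfg, pre_cfg, inf_cfg,
                            val_every = val_every, verbose = verbose,
                            retry_below = retry_below)
    if (!is.null(checkpoint_dir))
      save_checkpoint(fits[[f]]$model,
                      file.path(checkpoint_dir, paste0("fold", f), "best.ckpt"))
  }
  structure(list(fits = fits, plan = plan,
                 models = lapply(fits, `[[`, "model")),
            class = "seg_cv")
}

#' @export
print.seg_cv <- function(x, ...) {
  cat(sprintf("<seg_cv> %d folds\n", length(x$fits)))
  for (f in seq_along(x$fits))
    cat(sprintf("  fold %d: best Dice %.4f (epoch %d)\n", f,
                x$fits[[f]]$best_dice, x$fits[[f]]$best_epoch))
  invisible(x)
}
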