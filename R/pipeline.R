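#' Assemble a full run configuration
#'
#' Bundles every stage configuration plus paths and the master seed into a
#' serializable list; [run_pipeline()] writes the resolved configuration
#' next to its outputs so each run is reproducible from that file alone.
#'
#' @param model,optimizer,loss,augment,preprocess,inference,thresholds stage
#'   configurations (see the respective constructors).
#' @param phantom phantom generator configuration used when no training data
#'   directory is given.
#' @param n_train,n_test phantom counts when generating data.
#' @param k number of cross-validation folds.
#' @param val_every validation cadence in epochs.
#' @param retry_below per-fold convergence safeguard passed to
#'   [train_fold()] (default 0.75; see its documentation).
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(model = model_config("multires_unet3d", n_f = 4L, depth = 2L),
                       optimizer = optimizer_config(lr0 = 3e-3, epochs = 225L),
                       loss = loss_config(),
                       augment = augment_config(crop_shape = c(8L, 64L, 64L)),
                       preprocess = preprocess_config(),
                       inference = inference_config(window_slices = 8L),
                       thresholds = tissue_thresholds(),
                       phantom = phantom_config(),
                       n_train = 8L, n_test = 3L, k = 2L,
                       val_every = 25L, retry_below = 0.75, seed = 1L) {
  structure(list(model = model, optimizer = optimizer, loss = loss,
                 augment = augment, preprocess = preprocess,
                 inference = inference, thresholds = thresholds,
                 phantom = phantom, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), k = as.integer(k),
                 val_every = as.integer(val_every),
                 retry_below = retry_below, seed = as.integer(seed)),
            class = "run_config")
}

phantom_samples <- function(config, n, seed_base) {
  samples <- lapply(seq_len(n), function(i) {
    ph <- generate_phantom(config, seed = seed_base + i - 1L)
    list(ct = ph$ct, dense = ph$dense, sparse = ph$sparse,
         truth_counts = ph$truth_counts)
  })
  names(samples) <- sprintf("phantom%02d", seq_len(n))
  samples
}

#' Run the full phantom pipeline end to end
#'
#' Generates training and held-out test phantoms, trains one model per
#' cross-validation fold, predicts the test phantoms with the fold ensemble,
#' quantifies SAT/VAT/muscle volumes, and evaluates segmentation Dice and
#' per-tissue agreement (ICC, Bland-Altman) against the exact phantom
#' truth. All artifacts (checkpoints, label maps, per-slice CSV reports,
#' evaluation JSON, resolved configuration) are written under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param verbose print progress.
#' @return List with `cv` (the [train_seg_cv()] result), `dice`
#'   (per-test-volume mean foreground Dice), `agreement` (per tissue), and
#'   `out_dir`; class `bodycomp_run`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("bcrun"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(config, file.path(out_dir, "run_config.rds"))
  jsonlite::write_json(list(seed = config$seed, k = config$k,
                            n_train = config$n_train, n_test = config$n_test,
                            family = config$model$family,
                            n_f = config$model$n_f,
                            depth = config$model$depth),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  opt <- config$optimizer
  opt$seed <- config$seed
  train_samples <- phantom_samples(config$phantom, config$n_train,
                                   seed_base = config$seed * 1000L)
  test_samples <- phantom_samples(config$phantom, config$n_test,
                                  seed_base = config$seed * 1000L + 500L)
  cv <- train_seg_cv(train_samples, k = config$k, model_cfg = config$model,
                     opt_cfg = opt, loss_cfg = config$loss,
                     aug_cfg = config$augment, pre_cfg = config$preprocess,
                     inf_cfg = config$inference, val_every = config$val_every,
                     checkpoint_dir = file.path(out_dir, "checkpoints"),
                     verbose = verbose,
                     retry_below = config$retry_below %||% 0)
  dice <- numeric(0)
  pred_rows <- list(); truth_rows <- list()
  for (nm in names(test_samples)) {
    s <- test_samples[[nm]]
    probs <- ensemble_predict(cv$models, s$ct, config$preprocess,
                              config$inference)
    pred <- argmax_labels(probs, spacing = s$ct$spacing)
    write_label_map(pred, file.path(out_dir, paste0(nm, "_pred.nii.gz")))
    dice[nm] <- mean_dice(pred$labels, s$dense$labels)
    pr <- quantify_volumes(s$ct, pred, config$thresholds)
    tr <- quantify_volumes(s$ct, s$dense, config$thresholds)
    write_tissue_report(pr, csv_path = file.path(out_dir, paste0(nm, "_tissue.csv")),
                        json_path = file.path(out_dir, paste0(nm, "_totals.json")))
    pr$volume <- nm; tr$volume <- nm
    pred_rows[[nm]] <- as.data.frame(pr)
    truth_rows[[nm]] <- as.data.frame(tr)
  }
  pred_all <- do.call(rbind, pred_rows)
  truth_all <- do.call(rbind, truth_rows)
  # pool slices across test volumes for the agreement statistics
  pred_all$slice <- seq_len(nrow(pred_all))
  truth_all$slice <- seq_len(nrow(truth_all))
  agreement <- agreement_report(
    structure(pred_all, class = c("tissue_report", "data.frame")),
    structure(truth_all, class = c("tissue_report", "data.frame")),
    png_path = file.path(out_dir, "bland_altman.png"))
  eval_out <- list(
    mean_foreground_dice = mean(dice),
    dice_per_volume = as.list(dice),
    icc = lapply(agreement, `[[`, "icc"))
  jsonlite::write_json(eval_out, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(cv = cv, dice = dice, agreement = agreement,
                 out_dir = out_dir),
            class = "bodycomp_run")
}

#' @export
print.bodycomp_run <- function(x, ...) {
  cat("<bodycomp_run>\n")
  cat(sprintf("  mean foreground Dice on held-out phantoms: %.4f\n",
              mean(x$dice)))
  for (nm in names(x$agreement))
    cat(sprintf("  ICC %-6s: %.4f\n", nm, x$agreement[[nm]]$icc))
  cat("  artifacts:", x$out_dir, "\n")
  invisible(x)
}
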