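#' Synthetic abdominal CT phantom configuration
#'
#' The phantom emulates the topology and HU statistics of a 5-mm abdominal
#' CT: an elliptical body cross-section with, from the outside in, air
#' background, a subcutaneous fat ring, a muscle wall, and an internal
#' cavity; a vertebral body ("spine") of bone posteriorly; the top fraction
#' of slices is a thoracic cavity filled with lung-like low-HU tissue, the
#' rest an abdominal cavity containing visceral fat blobs among soft-tissue
#' "organs". Per-voxel HU are drawn from tissue-typical normal distributions
#' and clipped to the tissue's legal range, so every voxel's HU is
#' consistent with its region label and the fat/muscle threshold ranges.
#' Body radii vary smoothly along z so per-slice tissue volumes vary
#' from slice to slice.
#'
#' HU priors (mean, sd, clip range): subcutaneous/visceral fat
#' N(-100, 20) in `[-190, -30]`; muscle N(45, 15) in `[-29, 150]`; bone
#' N(400, 150) in `[151, 3071]`; abdominal soft tissue N(40, 20) in
#' `[-29, 150]`; lung N(-800, 50) in `[-1024, -191]`; background air -1024.
#'
#' @param shape integer `(n_slices, H, W)` grid size (default `c(20, 64, 64)`).
#' @param spacing voxel spacing `(dz, dy, dx)` mm (default `c(5, 2, 2)`).
#' @param body_radius_frac fraction of the half-extent covered by the body
#'   ellipse, `(ry, rx)` (default `c(0.76, 0.84)`; at the widest slices the body may just clip the lateral field of view, as real scans do).
#' @param subcut_frac,muscle_frac thickness of the subcutaneous ring and the
#'   muscle wall as fractions of the body radius (defaults 0.28, 0.22 — a
#'   2-3 cm subcutaneous layer at this grid scale, and thick enough that
#'   each layer spans several voxels at the network's halved in-plane
#'   resolution).
#' @param spine_frac spine ellipse radii as a fraction of the body radii
#'   (default 0.36); set to 0 to omit bone.
#' @param visceral_fat_frac scale of the visceral-fat blob coverage in the
#'   abdominal cavity (default 0.3; the realized covered fraction is
#'   substantially smaller because blobs overlap and clip at the cavity
#'   boundary — around 10-15% of the cavity at the default, a lean-patient
#'   amount). Set to 0 for a VAT-free phantom.
#' @param thoracic_frac fraction of slices (from the top, i.e. lowest z
#'   indices) whose cavity is thoracic (default 0.3, emulating an abdominal
#'   acquisition that includes the lung bases).
#' @param radius_wobble relative amplitude of the smooth along-z radius
#'   modulation (default 0.25, emulating the taper of the trunk from the
#'   ribcage through the waist; it drives the slice-to-slice volume
#'   variation that agreement statistics resolve).
#' @return A `phantom_config`.
#' @export
phantom_config <- function(shape = c(20L, 64L, 64L), spacing = c(5, 2, 2),
                           body_radius_frac = c(0.76, 0.84),
                           subcut_frac = 0.28, muscle_frac = 0.22,
                           spine_frac = 0.36, visceral_fat_frac = 0.3,
                           thoracic_frac = 0.30, radius_wobble = 0.25) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) bc_stop("shape must be (z, y, x), each >= 4")
  if (any(body_radius_frac <= 0) || any(body_radius_frac > 0.92))
    bc_stop("body_radius_frac out of range")
  if (subcut_frac + muscle_frac >= 0.9)
    bc_stop("subcutaneous ring plus muscle wall leave no cavity")
  if (visceral_fat_frac < 0 || visceral_fat_frac > 0.8)
    bc_stop("visceral_fat_frac out of [0, 0.8]")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 body_radius_frac = body_radius_frac,
                 subcut_frac = subcut_frac, muscle_frac = muscle_frac,
                 spine_frac = spine_frac,
                 visceral_fat_frac = visceral_fat_frac,
                 thoracic_frac = thoracic_frac,
                 radius_wobble = radius_wobble),
            class = "phantom_config")
}

# HU priors per tissue: normal draw clipped to the tissue's legal HU range.
PHANTOM_HU <- list(
  fat    = list(mean = -100, sd = 20,  lo = -190,  hi = -30),
  muscle = list(mean = 45,   sd = 15,  lo = -29,   hi = 150),
  bone   = list(mean = 400,  sd = 150, lo = 151,   hi = 3071),
  organ  = list(mean = 40,   sd = 20,  lo = -29,   hi = 150),
  lung   = list(mean = -800, sd = 50,  lo = -1024, hi = -191)
)

draw_hu <- function(n, tissue) {
  p <- PHANTOM_HU[[tissue]]
  round(pmin(p$hi, pmax(p$lo, rnorm(n, p$mean, p$sd))))
}

#' Generate a synthetic abdominal CT phantom with exact ground truth
#'
#' Deterministic under `seed`. Returns the CT volume, the dense label map,
#' a sparse label map with only every `annotation_stride`-th slice annotated
#' (the rest ignore), and exact per-slice voxel counts of
#' adipose-range-in-subcutaneous (SAT), adipose-range-in-abdominal-cavity
#' (VAT) and muscle-range-in-muscle-region (muscle) voxels, enumerated
#' during synthesis.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @param annotation_stride annotate every k-th slice (default 5).
#' @return List with elements `ct` ([ct_volume()]), `dense` ([label_map()]),
#'   `sparse` ([label_map()]), and `truth_counts` (data.frame with columns
#'   `slice`, `sat_voxels`, `vat_voxels`, `muscle_voxels`).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L,
                             annotation_stride = 5L) {
  stopifnot(inherits(config, "phantom_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  d <- config$shape
  nz <- d[1]; H <- d[2]; W <- d[3]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ry0 <- config$body_radius_frac[1] * (H - 1) / 2
  rx0 <- config$body_radius_frac[2] * (W - 1) / 2
  if (ry0 < 4 || rx0 < 4) bc_stop("body radii too small for the grid")
  # smooth along-z modulation of the body radii, plus a small random phase
  phase <- runif(1, 0, 2 * pi)
  mod <- 1 + config$radius_wobble * sin(seq_len(nz) / nz * pi + phase)
  n_thor <- floor(config$thoracic_frac * nz)

  hu <- array(BC_HU_MIN, d)
  labels <- array(BC_CODES[["background"]], d)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)

  for (z in seq_len(nz)) {
    ry <- ry0 * mod[z]; rx <- rx0 * mod[z]
    r <- sqrt(((yy - cy) / ry)^2 + ((xx - cx) / rx)^2)
    s_musc <- 1 - config$subcut_frac     # inner edge of the subcut ring
    s_cav <- s_musc - config$muscle_frac # inner edge of the muscle wall
    sl_lab <- matrix(BC_CODES[["background"]], H, W)
    sl_lab[r <= 1] <- BC_CODES[["subcutaneous"]]
    sl_lab[r <= s_musc] <- BC_CODES[["muscle"]]
    cavity_code <- if (z <= n_thor) BC_CODES[["thoracic_cavity"]] else
      BC_CODES[["abdominal_cavity"]]
    sl_lab[r <= s_cav] <- cavity_code

    # spine: bone ellipse at the posterior cavity edge (larger y)
    if (config$spine_frac > 0) {
      sy <- cy + 0.60 * ry * s_cav
      rb_y <- config$spine_frac * ry * 0.5
      rb_x <- config$spine_frac * rx * 0.5
      rb <- sqrt(((yy - sy) / rb_y)^2 + ((xx - cx) / rb_x)^2)
      sl_lab[rb <= 1 & r <= s_musc] <- BC_CODES[["bones"]]
    }

    sl_hu <- matrix(BC_HU_MIN, H, W)
    sub_i <- sl_lab == BC_CODES[["subcutaneous"]]
    mus_i <- sl_lab == BC_CODES[["muscle"]]
    bon_i <- sl_lab == BC_CODES[["bones"]]
    sl_hu[sub_i] <- draw_hu(sum(sub_i), "fat")
    sl_hu[mus_i] <- draw_hu(sum(mus_i), "muscle")
    sl_hu[bon_i] <- draw_hu(sum(bon_i), "bone")

    cav_i <- sl_lab == cavity_code
    if (cavity_code == BC_CODES[["thoracic_cavity"]]) {
      sl_hu[cav_i] <- draw_hu(sum(cav_i), "lung")
    } else {
      # visceral fat blobs among soft-tissue organs
      fat_mask <- matrix(FALSE, H, W)
      if (config$visceral_fat_frac > 0 && sum(cav_i) > 0) {
        n_blob <- 3L + sample.int(3L, 1L)
        cav_idx <- which(cav_i, arr.ind = TRUE)
        for (b in seq_len(n_blob)) {
          ci <- cav_idx[sample.int(nrow(cav_idx), 1L), ]
          br <- sqrt(config$visceral_fat_frac) *
            max(3, 0.35 * s_cav * min(ry, rx)) * runif(1, 0.6, 1.1)
          bb <- sqrt((yy - ci[1])^2 + (xx - ci[2])^2)
          fat_mask <- fat_mask | (bb <= br)
        }
        fat_mask <- fat_mask & cav_i
      }
      org_i <- cav_i & !fat_mask
      sl_hu[fat_mask] <- draw_hu(sum(fat_mask), "fat")
      sl_hu[org_i] <- draw_hu(sum(org_i), "organ")
    }
    hu[z, , ] <- sl_hu
    labels[z, , ] <- sl_lab
  }

  ct <- ct_volume(hu, spacing = config$spacing)
  dense <- label_map(labels, spacing = config$spacing)
  sparse <- sparsify_annotations(dense, stride = annotation_stride)

  fat_rng <- hu >= -190 & hu <= -30
  mus_rng <- hu >= -29 & hu <= 150
  per_slice <- function(mask) as.integer(apply(mask, 1, sum))
  truth <- data.frame(
    slice = seq_len(nz),
    sat_voxels = per_slice(fat_rng & labels == BC_CODES[["subcutaneous"]]),
    vat_voxels = per_slice(fat_rng & labels == BC_CODES[["abdominal_cavity"]]),
    muscle_voxels = per_slice(mus_rng & labels == BC_CODES[["muscle"]]))
  list(ct = ct, dense = dense, sparse = sparse, truth_counts = truth)
}

#' Keep every k-th slice annotated, mark the rest ignore
#'
#' Emulates the sparse annotation protocol in which only every fifth axial
#' slice is labelled. Slices 1, 1+stride, 1+2*stride, ... keep their labels;
#' all other slices are set to the ignore code.
#'
#' @param dense a [label_map()].
#' @param stride integer >= 1 (1 returns the input unchanged).
#' @return A [label_map()].
#' @export
sparsify_annotations <- function(dense, stride = 5L) {
  stopifnot(inherits(dense, "label_map"))
  stride <- as.integer(stride)
  if (stride < 1L) bc_stop("stride must be >= 1")
  if (stride == 1L) return(dense)
  l <- dense$labels
  nz <- dim(l)[1]
  keep <- seq(1L, nz, by = stride)
  out <- array(BC_IGNORE, dim(l))
  out[keep, , ] <- l[keep, , ]
  label_map(out, spacing = dense$spacing)
}

#' Write a set of phantoms to disk
#'
#' Writes `n` phantoms as NIfTI volume + dense and sparse label maps plus a
#' truth-count CSV each, under `out_dir/phantom<i>_*`.
#'
#' @param n number of phantoms.
#' @param out_dir output directory (created if needed).
#' @param config a [phantom_config()].
#' @param seed base seed; phantom i uses `seed + i - 1`.
#' @return Data frame manifest with one row per phantom, invisibly.
#' @export
write_phantom_set <- function(n, out_dir, config = phantom_config(), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    ph <- generate_phantom(config, seed = seed + i - 1L)
    base <- file.path(out_dir, sprintf("phantom%02d", i))
    write_ct_volume(ph$ct, paste0(base, "_ct.nii.gz"))
    write_label_map(ph$dense, paste0(base, "_dense.nii.gz"))
    write_label_map(ph$sparse, paste0(base, "_sparse.nii.gz"))
    write.csv(ph$truth_counts, paste0(base, "_truth.csv"), row.names = FALSE)
    data.frame(id = sprintf("phantom%02d", i),
               ct = paste0(base, "_ct.nii.gz"),
               dense = paste0(base, "_dense.nii.gz"),
               sparse = paste0(base, "_sparse.nii.gz"),
               truth = paste0(base, "_truth.csv"))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
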