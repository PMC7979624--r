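#' HU threshold ranges for tissue subclassification
#'
#' Adipose tissue is any voxel with HU in `[-190, -30]`, muscular tissue any
#' voxel in `[-29, 150]` (both bounds inclusive; the two integer ranges are
#' adjacent and disjoint). The tissue assignment is a logical conjunction of
#' the HU range and the predicted semantic region: adipose HU in the
#' abdominal cavity counts as VAT, adipose HU in the subcutaneous region as
#' SAT, muscle-range HU in the muscle region as muscle; everything else
#' counts as no tissue.
#'
#' @param adipose integer `(lo, hi)` HU range for fat (default
#'   `c(-190, -30)`).
#' @param muscle integer `(lo, hi)` HU range for muscle (default
#'   `c(-29, 150)`).
#' @return A `tissue_thresholds`.
#' @export
tissue_thresholds <- function(adipose = c(-190L, -30L), muscle = c(-29L, 150L)) {
  adipose <- as.integer(adipose); muscle <- as.integer(muscle)
  if (length(adipose) != 2L || length(muscle) != 2L ||
      adipose[1] > adipose[2] || muscle[1] > muscle[2])
    bc_stop("threshold ranges must be (lo, hi) with lo <= hi")
  if (adipose[2] >= muscle[1] && muscle[2] >= adipose[1])
    bc_stop("adipose and muscle HU ranges must be disjoint")
  structure(list(adipose = adipose, muscle = muscle),
            class = "tissue_thresholds")
}

#' Subclassify voxels by HU range and semantic region
#'
#' Vectorized over `hu` and `region`.
#'
#' @param hu numeric HU values.
#' @param region integer region codes (0..5, 255 = ignore).
#' @param thresholds a [tissue_thresholds()].
#' @return Character vector in `{"SAT", "VAT", "muscle", "none"}`.
#' @examples
#' classify_voxel(-100, 4)  # adipose HU in the abdominal cavity -> "VAT"
#' classify_voxel(-100, 3)  # same HU under the skin -> "SAT"
#' classify_voxel(50, 4)    # muscle-range HU inside the cavity -> "none"
#' @export
classify_voxel <- function(hu, region, thresholds = tissue_thresholds()) {
  stopifnot(inherits(thresholds, "tissue_thresholds"))
  fat <- hu >= thresholds$adipose[1] & hu <= thresholds$adipose[2]
  mus <- hu >= thresholds$muscle[1] & hu <= thresholds$muscle[2]
  out <- rep("none", length(hu))
  out[fat & region == BC_CODES[["abdominal_cavity"]]] <- "VAT"
  out[fat & region == BC_CODES[["subcutaneous"]]] <- "SAT"
  out[mus & region == BC_CODES[["muscle"]]] <- "muscle"
  out
}

#' Per-slice and total SAT/VAT/muscle volumes
#'
#' Counts tissue voxels per axial slice via [classify_voxel()] and converts
#' to millilitres with the voxel volume `dz * dy * dx` (mm^3 -> mL).
#' Ignore-labelled voxels (e.g. unannotated slices of a ground-truth map)
#' contribute nothing. Quantification is exact integer counting; the only
#' floating-point step is the final unit conversion.
#'
#' @param ct a [ct_volume()].
#' @param labels a [label_map()] at the same (native) resolution.
#' @param thresholds a [tissue_thresholds()].
#' @return A `tissue_report`: data.frame with columns `slice`, `sat_ml`,
#'   `vat_ml`, `muscle_ml` and attributes `totals` (named numeric) and
#'   `voxel_volume_mm3`.
#' @export
quantify_volumes <- function(ct, labels, thresholds = tissue_thresholds()) {
  stopifnot(inherits(ct, "ct_volume"), inherits(labels, "label_map"))
  if (!identical(dim(ct$voxels), dim(labels$labels)))
    bc_stop("CT and label grids differ in shape")
  if (any(!is.finite(ct$spacing)) || any(ct$spacing <= 0))
    bc_stop("CT volume has no valid voxel spacing")
  vox_mm3 <- prod(ct$spacing)
  d <- dim(ct$voxels)
  cls <- classify_voxel(as.numeric(ct$voxels), as.integer(labels$labels),
                        thresholds)
  dim(cls) <- d
  count_slice <- function(what) apply(cls == what, 1, sum)
  rep_df <- data.frame(slice = seq_len(d[1]),
                       sat_ml = count_slice("SAT") * vox_mm3 / 1000,
                       vat_ml = count_slice("VAT") * vox_mm3 / 1000,
                       muscle_ml = count_slice("muscle") * vox_mm3 / 1000)
  structure(rep_df,
            totals = c(sat_ml = sum(rep_df$sat_ml), vat_ml = sum(rep_df$vat_ml),
                       muscle_ml = sum(rep_df$muscle_ml)),
            voxel_volume_mm3 = vox_mm3,
            class = c("tissue_report", "data.frame"))
}

#' @export
print.tissue_report <- function(x, ...) {
  t <- attr(x, "totals")
  cat(sprintf("<tissue_report> %d slices, voxel %.3f mm^3\n",
              nrow(x), attr(x, "voxel_volume_mm3")))
  cat(sprintf("  totals: SAT %.1f mL, VAT %.1f mL, muscle %.1f mL\n",
              t[["sat_ml"]], t[["vat_ml"]], t[["muscle_ml"]]))
  invisible(x)
}

#' Stacked per-slice tissue volume bar plot
#'
#' @param x a `tissue_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.tissue_report <- function(x, ...) {
  m <- t(as.matrix(x[, c("muscle_ml", "sat_ml", "vat_ml")]))
  graphics::barplot(m, names.arg = x$slice, col = c("gold", "firebrick", "forestgreen"),
                    border = NA, xlab = "axial slice", ylab = "volume (mL)",
                    legend.text = c("muscle", "SAT", "VAT"), ...)
  invisible(x)
}

#' Write a tissue report to CSV (per-slice) and JSON (totals)
#'
#' @param report a `tissue_report`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_tissue_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(attr(report, "totals")), json_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Agreement between predicted and ground-truth tissue volumes
#'
#' Per-tissue ICC(2,1) and Bland-Altman statistics over matched slices
#' (typically the annotated slices only). Optionally writes a Bland-Altman
#' panel PNG.
#'
#' @param pred_report,truth_report `tissue_report`s with matching slice
#'   indices.
#' @param slices optional integer subset of slice indices to compare
#'   (default: all slices present in both).
#' @param png_path optional output path for a Bland-Altman panel plot.
#' @return List with one element per tissue (`sat`, `vat`, `muscle`), each
#'   holding `icc` and the [bland_altman()] statistics.
#' @export
agreement_report <- function(pred_report, truth_report, slices = NULL,
                             png_path = NULL) {
  common <- intersect(pred_report$slice, truth_report$slice)
  if (!is.null(slices)) common <- intersect(common, slices)
  if (length(common) < 3L)
    bc_stop("need at least 3 matched slices for agreement statistics")
  p <- pred_report[match(common, pred_report$slice), ]
  t <- truth_report[match(common, truth_report$slice), ]
  cols <- c(sat = "sat_ml", vat = "vat_ml", muscle = "muscle_ml")
  out <- lapply(cols, function(cl) {
    ba <- bland_altman(p[[cl]], t[[cl]])
    c(list(icc = icc(p[[cl]], t[[cl]])), ba)
  })
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 1200, height = 420)
    old <- graphics::par(mfrow = c(1, 3))
    on.exit({ graphics::par(old); grDevices::dev.off() }, add = TRUE)
    for (nm in names(cols)) {
      ba <- out[[nm]]
      graphics::plot(ba$means, ba$diffs, pch = 19,
                     xlab = "mean of methods (mL)",
                     ylab = "difference (mL)", main = toupper(nm))
      graphics::abline(h = c(ba$bias, ba$loa_lo, ba$loa_hi),
                       lty = c(1, 2, 2), col = "steelblue")
    }
  }
  out
}
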