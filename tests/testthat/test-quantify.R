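test_that("voxel subclassification follows the HU-range / region conjunction", {
  th <- tissue_thresholds()
  expect_equal(classify_voxel(-100, 4), "VAT")
  expect_equal(classify_voxel(-100, 3), "SAT")
  expect_equal(classify_voxel(50, 1), "muscle")
  expect_equal(classify_voxel(50, 4), "none")    # muscle-range HU, wrong region
  expect_equal(classify_voxel(-100, 1), "none")  # fat-range HU in muscle region
  expect_equal(classify_voxel(-100, 0), "none")
  # inclusive integer boundaries: -30 is adipose, -29 is muscle
  expect_equal(classify_voxel(-30, 4), "VAT")
  expect_equal(classify_voxel(-29, 4), "none")
  expect_equal(classify_voxel(-29, 1), "muscle")
  expect_equal(classify_voxel(-190, 3), "SAT")
  expect_equal(classify_voxel(-191, 3), "none")
  expect_equal(classify_voxel(150, 1), "muscle")
  expect_equal(classify_voxel(151, 1), "none")
  expect_error(tissue_thresholds(adipose = c(-190, 0)), "disjoint")
})

test_that("every voxel contributes to at most one tissue class", {
  set.seed(41)
  hu <- sample(-1024:3071, 5000, TRUE)
  region <- sample(c(0:5, 255L), 5000, TRUE)
  cls <- classify_voxel(hu, region)
  expect_true(all(cls %in% c("SAT", "VAT", "muscle", "none")))
  # conjunction: a tissue voxel must satisfy both the range and the region
  expect_true(all(region[cls == "VAT"] == 4 & hu[cls == "VAT"] >= -190 &
                    hu[cls == "VAT"] <= -30))
  expect_true(all(region[cls == "muscle"] == 1))
})

test_that("volumes are voxel counts times voxel volume, in mL", {
  # 1000 fat voxels in the abdominal cavity at spacing (5, 0.8, 0.8) mm:
  # 1000 * 3.2 mm^3 = 3.2 mL on that slice
  hu <- array(50, c(2, 40, 40))
  hu[1, 1:25, ] <- -100                      # 1000 voxels on slice 1
  lab <- array(0L, c(2, 40, 40))
  lab[1, 1:25, ] <- 4L
  ct <- ct_volume(hu, spacing = c(5, 0.8, 0.8))
  rep <- quantify_volumes(ct, label_map(lab, ct$spacing))
  expect_equal(rep$vat_ml[1], 3.2)
  expect_equal(rep$vat_ml[2], 0)
  expect_equal(rep$sat_ml, c(0, 0))
  expect_equal(attr(rep, "totals")[["vat_ml"]], 3.2)

  # all-background label map gives all-zero volumes
  rep0 <- quantify_volumes(ct, label_map(array(0L, dim(hu)), ct$spacing))
  expect_true(all(as.matrix(rep0[, -1]) == 0))
})

test_that("report totals equal the per-slice column sums", {
  ph <- generate_phantom(tiny_phantom_config(), seed = 6)
  rep <- quantify_volumes(ph$ct, ph$dense)
  t <- attr(rep, "totals")
  expect_equal(t[["sat_ml"]], sum(rep$sat_ml), tolerance = 1e-9)
  expect_equal(t[["vat_ml"]], sum(rep$vat_ml), tolerance = 1e-9)
  expect_equal(t[["muscle_ml"]], sum(rep$muscle_ml), tolerance = 1e-9)
  expect_true(all(as.matrix(rep[, -1]) >= 0))
})

test_that("quantifying ground-truth labels reproduces the generator's counts", {
  cfg <- tiny_phantom_config()
  for (seed in c(1, 9)) {
    ph <- generate_phantom(cfg, seed = seed)
    rep <- quantify_volumes(ph$ct, ph$dense)
    vox_ml <- prod(cfg$spacing) / 1000
    expect_equal(rep$sat_ml, ph$truth_counts$sat_voxels * vox_ml)
    expect_equal(rep$vat_ml, ph$truth_counts$vat_voxels * vox_ml)
    expect_equal(rep$muscle_ml, ph$truth_counts$muscle_voxels * vox_ml)
  }
})

test_that("ignore-labelled voxels are excluded from quantification", {
  ph <- generate_phantom(tiny_phantom_config(), seed = 3)
  rep_sparse <- quantify_volumes(ph$ct, ph$sparse)
  annotated <- seq(1, dim(ph$ct$voxels)[1], by = 5)
  rep_dense <- quantify_volumes(ph$ct, ph$dense)
  expect_equal(rep_sparse$sat_ml[annotated], rep_dense$sat_ml[annotated])
  expect_true(all(rep_sparse$sat_ml[-annotated] == 0))
})

test_that("agreement report: perfect agreement, plotting, and minimum size", {
  ph <- generate_phantom(tiny_phantom_config(), seed = 2)
  rep <- quantify_volumes(ph$ct, ph$dense)
  png <- tempfile(fileext = ".png")
  agr <- agreement_report(rep, rep, png_path = png)
  for (nm in c("sat", "vat", "muscle")) {
    expect_equal(agr[[nm]]$icc, 1)
    expect_equal(agr[[nm]]$bias, 0)
  }
  expect_true(file.exists(png))
  expect_error(agreement_report(rep[1, ], rep[1, ]), "at least 3")
})

test_that("tissue report writes the per-slice CSV schema and JSON totals", {
  ph <- generate_phantom(tiny_phantom_config(), seed = 8)
  rep <- quantify_volumes(ph$ct, ph$dense)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_tissue_report(rep, csv, js)
  got <- read.csv(csv)
  expect_identical(names(got), c("slice", "sat_ml", "vat_ml", "muscle_ml"))
  expect_equal(nrow(got), nrow(rep))
  tot <- jsonlite::read_json(js)
  expect_equal(tot$sat_ml, attr(rep, "totals")[["sat_ml"]], tolerance = 1e-9)
})
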