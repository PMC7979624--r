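test_that("HU clipping enforces the 12-bit scanner range and is idempotent", {
  v <- array(c(-2000, -1024, 0, 3071, 4000, 500), c(1, 2, 3))
  ct <- ct_volume(v, spacing = c(5, 1, 1))
  expect_equal(range(ct$voxels), c(-1024, 3071))
  expect_equal(ct$voxels[1, 1, 1], -1024)  # -2000 clipped up
  expect_equal(ct$voxels[1, 1, 3], 3071)   # 4000 clipped down
  expect_identical(clip_hu(clip_hu(v)), clip_hu(v))
})

test_that("ct_volume validates spacing and shape", {
  expect_error(ct_volume(array(0, c(2, 2)), c(5, 1, 1)), "3D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(5, 0, 1)), "positive")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(5, 1)), "positive|three")
})

test_that("CT volumes round-trip voxel-identically through NIfTI", {
  set.seed(1)
  v <- array(sample(-1024:2000, 5 * 6 * 7, TRUE), c(5, 6, 7))
  ct <- ct_volume(v, spacing = c(5, 0.8, 0.7))
  path <- tempfile(fileext = ".nii.gz")
  write_ct_volume(ct, path)
  ct2 <- read_ct_volume(path)
  expect_equal(ct2$voxels, ct$voxels, ignore_attr = TRUE)
  expect_equal(ct2$spacing, ct$spacing, tolerance = 1e-6)
})

test_that("label maps round-trip through NIfTI and reject bad codes", {
  set.seed(2)
  l <- array(sample(c(0:5, 255L), 4 * 5 * 5, TRUE), c(4, 5, 5))
  lm <- label_map(l, spacing = c(5, 1, 1))
  path <- tempfile(fileext = ".nii.gz")
  write_label_map(lm, path)
  lm2 <- read_label_map(path)
  expect_identical(lm2$labels, lm$labels)

  expect_error(label_map(array(7L, c(2, 2, 2)), c(5, 1, 1)), "7")
  expect_error(label_map(array(c(0L, 9L, 12L, 1L), c(1, 2, 2)), c(5, 1, 1)),
               "9, 12")
  # an all-ignore grid is legal (an entirely unannotated block)
  expect_s3_class(label_map(array(255L, c(2, 2, 2)), c(5, 1, 1)), "label_map")
})

test_that("DICOM series read applies rescale, sorts slices, fills spacing", {
  dir <- write_test_dicom_series(tempfile("dcm"), n_slices = 4, rows = 6,
                                 cols = 5, dz = 5)
  ct <- read_ct_volume(dir, format = "dicom_dir")
  expect_equal(dim(ct$voxels), c(4, 6, 5))
  expect_equal(ct$spacing, c(5, 0.8, 0.7), tolerance = 1e-9)
  # stored value v with slope 1, intercept -1024 -> HU = v - 1024
  px <- matrix(seq_len(30) + 100L, 6, 5)
  expect_equal(ct$voxels[1, , ], px - 1024, ignore_attr = TRUE)

  # stored 0 / slope 1 / intercept -1024 gives exactly -1024 HU
  d2 <- tempfile("dcm0"); dir.create(d2)
  write_test_dicom(file.path(d2, "a.dcm"), matrix(0L, 2, 2), z = 0)
  write_test_dicom(file.path(d2, "b.dcm"), matrix(0L, 2, 2), z = 5)
  ct0 <- read_ct_volume(d2)
  expect_true(all(ct0$voxels == -1024))

  # stored HU above the 12-bit ceiling is clipped to 3071
  d3 <- tempfile("dcmhi"); dir.create(d3)
  write_test_dicom(file.path(d3, "a.dcm"), matrix(5024L, 2, 2), z = 0,
                   intercept = 0)
  write_test_dicom(file.path(d3, "b.dcm"), matrix(5024L, 2, 2), z = 5,
                   intercept = 0)
  expect_true(all(read_ct_volume(d3)$voxels == 3071))
})

test_that("DICOM reader rejects broken series with informative errors", {
  # non-CT modality
  d <- tempfile("dcmmr"); dir.create(d)
  write_test_dicom(file.path(d, "a.dcm"), matrix(0L, 2, 2), z = 0,
                   modality = "MR")
  expect_error(read_ct_volume(d), "Modality")

  # varying in-plane spacing: refuse to resample
  d2 <- tempfile("dcmsp"); dir.create(d2)
  write_test_dicom(file.path(d2, "a.dcm"), matrix(0L, 2, 2), z = 0)
  write_test_dicom(file.path(d2, "b.dcm"), matrix(0L, 2, 2), z = 5,
                   pixel_spacing = c(0.9, 0.7))
  expect_error(read_ct_volume(d2), "spacing.*b\\.dcm|b\\.dcm")

  # irregular slice spacing names the offending file
  d3 <- tempfile("dcmz"); dir.create(d3)
  for (z in c(0, 5, 12)) write_test_dicom(file.path(d3, sprintf("s%02d.dcm", z)),
                                          matrix(0L, 2, 2), z = z)
  expect_error(read_ct_volume(d3), "slice spacing")

  # missing slice position
  d4 <- tempfile("dcmnp"); dir.create(d4)
  write_test_dicom(file.path(d4, "a.dcm"), matrix(0L, 2, 2),
                   omit_position = TRUE)
  expect_error(read_ct_volume(d4), "position")
})
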