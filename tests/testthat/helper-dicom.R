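# Byte-level writer for minimal explicit-VR little-endian CT DICOM slices.
# Intentionally independent of the package's reader so round-trip tests
# exercise two separate code paths.

le16 <- function(x) as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
le32 <- function(x) as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L),
                             bitwAnd(bitwShiftR(x, 16L), 255L),
                             bitwAnd(bitwShiftR(x, 24L), 255L)))

dcm_elem <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    len <- len + 1L
  }
  head <- c(le16(group), le16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0L, 0L)), le32(len), value_raw)
  else
    c(head, le16(len), value_raw)
}

dcm_str <- function(group, elem, vr, s) dcm_elem(group, elem, vr, charToRaw(s))
dcm_us <- function(group, elem, x) dcm_elem(group, elem, "US", le16(as.integer(x)))

# pixels: integer matrix (rows x cols), stored values (pre-rescale),
# written row-major as signed 16-bit.
write_test_dicom <- function(path, pixels, z = 0, slope = 1, intercept = -1024,
                             pixel_spacing = c(0.8, 0.7), modality = "CT",
                             orientation = c(1, 0, 0, 0, 1, 0),
                             transfer_syntax = "1.2.840.10008.1.2.1",
                             omit_position = FALSE) {
  stopifnot(is.matrix(pixels))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  # file meta group (always explicit VR)
  writeBin(dcm_str(0x0002, 0x0010, "UI", transfer_syntax), con)
  # dataset (explicit VR little endian assumed by this writer)
  writeBin(dcm_str(0x0008, 0x0060, "CS", modality), con)
  if (!omit_position)
    writeBin(dcm_str(0x0020, 0x0032, "DS",
                     sprintf("0\\0\\%g", z)), con)
  writeBin(dcm_str(0x0020, 0x0037, "DS",
                   paste(orientation, collapse = "\\")), con)
  writeBin(dcm_us(0x0028, 0x0010, nrow(pixels)), con)
  writeBin(dcm_us(0x0028, 0x0011, ncol(pixels)), con)
  writeBin(dcm_str(0x0028, 0x0030, "DS",
                   sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2])), con)
  writeBin(dcm_us(0x0028, 0x0002, 1L), con)              # SamplesPerPixel
  writeBin(dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"), con)
  writeBin(dcm_us(0x0028, 0x0100, 16L), con)             # BitsAllocated
  writeBin(dcm_us(0x0028, 0x0101, 16L), con)             # BitsStored
  writeBin(dcm_us(0x0028, 0x0102, 15L), con)             # HighBit
  writeBin(dcm_us(0x0028, 0x0103, 1L), con)              # PixelRepresentation
  writeBin(dcm_str(0x0028, 0x1052, "DS", sprintf("%g", intercept)), con)
  writeBin(dcm_str(0x0028, 0x1053, "DS", sprintf("%g", slope)), con)
  vals <- as.integer(t(pixels))  # row-major
  buf <- writeBin(vals, raw(), size = 2L, endian = "little")
  writeBin(dcm_elem(0x7FE0, 0x0010, "OW", buf), con)
  invisible(path)
}

write_test_dicom_series <- function(dir, n_slices = 3, rows = 4, cols = 5,
                                    dz = 5, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_slices)) {
    px <- matrix(seq_len(rows * cols) + 100L * i, rows, cols)
    write_test_dicom(file.path(dir, sprintf("slice%02d.dcm", i)), px,
                     z = (i - 1) * dz, ...)
  }
  dir
}
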