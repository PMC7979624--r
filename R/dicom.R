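# Minimal DICOM series reader for uncompressed CT slices.
#
# Scope: little-endian transfer syntaxes only (implicit VR 1.2.840.10008.1.2
# and explicit VR 1.2.840.10008.1.2.1), 16-bit pixel data, no compressed
# pixel encapsulation and no undefined-length sequences. That covers plain
# axial CT series as exported by scanners; anything else is rejected with a
# clear error rather than guessed at.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

u16 <- function(raw, off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
u32 <- function(raw, off) {
  as.numeric(raw[off + 1]) + 256 * as.numeric(raw[off + 2]) +
    65536 * as.numeric(raw[off + 3]) + 16777216 * as.numeric(raw[off + 4])
}

# VRs that use the 4-byte length form (with 2 reserved bytes) in explicit VR.
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    bc_stop("not a DICOM part-10 file: ", path)
  off <- 132L  # 0-based offset just past "DICM"
  ts <- TS_EXPLICIT_LE
  tags <- list()
  n <- length(raw)
  in_meta_checked <- FALSE
  while (off + 8 <= n) {
    group <- u16(raw, off); elem <- u16(raw, off + 2L)
    explicit <- (group == 0x0002) || ts == TS_EXPLICIT_LE
    if (explicit) {
      vr <- rawToChar(raw[(off + 5):(off + 6)])
      if (vr %in% LONG_VRS) {
        len <- u32(raw, off + 8L); hdr <- 12L
      } else {
        len <- u16(raw, off + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(raw, off + 4L); hdr <- 8L
    }
    if (len == 4294967295)
      bc_stop("undefined-length element (", sprintf("%04X,%04X", group, elem),
              ") not supported: ", path)
    val_off <- off + hdr
    if (val_off + len > n) bc_stop("truncated DICOM element in ", path)
    key <- sprintf("%04X,%04X", group, elem)
    body <- raw[seq_len(len) + val_off]
    tags[[key]] <- list(vr = vr, bytes = body)
    off <- val_off + as.integer(len)
    if (group == 0x0002 && elem == 0x0010) {
      ts <- raw_to_string(body)
      if (!ts %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE))
        bc_stop("unsupported transfer syntax ", ts, " in ", path)
      in_meta_checked <- TRUE
    }
  }
  if (!in_meta_checked) ts <- TS_EXPLICIT_LE
  tags
}

# Strings in DICOM are padded to even length with spaces (or NUL for UIDs).
raw_to_string <- function(bytes) {
  while (length(bytes) && bytes[length(bytes)] %in% as.raw(c(0L, 32L)))
    bytes <- bytes[-length(bytes)]
  trimws(rawToChar(bytes))
}

tag_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_character_)
  raw_to_string(t$bytes)
}

tag_ds <- function(tags, key) {
  s <- tag_str(tags, key)
  if (is.na(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

tag_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  u16(t$bytes, 0L)
}

read_dicom_slice <- function(path) {
  tags <- parse_dicom_file(path)
  modality <- tag_str(tags, "0008,0060")
  if (is.na(modality) || modality != "CT")
    bc_stop("not a CT modality DICOM file (Modality = ",
            ifelse(is.na(modality), "<missing>", modality), "): ", path)
  rows <- tag_us(tags, "0028,0010"); cols <- tag_us(tags, "0028,0011")
  bits <- tag_us(tags, "0028,0100"); signed <- tag_us(tags, "0028,0103")
  if (is.null(rows) || is.null(cols)) bc_stop("missing Rows/Columns in ", path)
  if (is.null(bits) || bits != 16L) bc_stop("only 16-bit pixel data supported: ", path)
  px <- tags[["7FE0,0010"]]
  if (is.null(px)) bc_stop("missing PixelData in ", path)
  v <- readBin(px$bytes, "integer", n = rows * cols, size = 2,
               signed = !identical(signed, 0L), endian = "little")
  slope <- tag_ds(tags, "0028,1053"); inter <- tag_ds(tags, "0028,1052")
  if (is.null(slope)) slope <- 1
  if (is.null(inter)) inter <- 0
  pos <- tag_ds(tags, "0020,0032")
  zloc <- if (!is.null(pos)) pos[3] else tag_ds(tags, "0020,1041")
  if (is.null(zloc) || is.na(zloc))
    bc_stop("cannot determine slice position (no ImagePositionPatient or ",
            "SliceLocation): ", path)
  list(hu = matrix(v, nrow = rows, ncol = cols, byrow = TRUE) * slope + inter,
       z = zloc,
       pixel_spacing = tag_ds(tags, "0028,0030"),
       orientation = tag_ds(tags, "0020,0037"),
       path = path)
}

#' Read a DICOM series directory as a CT volume
#'
#' All files in `path` are parsed as uncompressed little-endian CT slices,
#' sorted by slice position, rescaled to HU and clipped to `[-1024, 3071]`.
#' Series with inconsistent orientation or in-plane pixel spacing, or with
#' irregular slice spacing, are rejected (silently resampling them would
#' corrupt downstream volumetry).
#'
#' @param path directory containing one DICOM file per slice.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(path) {
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files)) bc_stop("no files in DICOM directory: ", path)
  slices <- lapply(files, read_dicom_slice)
  ps <- slices[[1]]$pixel_spacing
  if (is.null(ps) || length(ps) != 2)
    bc_stop("missing PixelSpacing in ", slices[[1]]$path)
  for (s in slices) {
    if (is.null(s$pixel_spacing) || max(abs(s$pixel_spacing - ps)) > 1e-6)
      bc_stop("in-plane pixel spacing varies across the series (offending file: ",
              s$path, "); refusing to resample")
    if (!is.null(slices[[1]]$orientation) && !is.null(s$orientation) &&
        max(abs(s$orientation - slices[[1]]$orientation)) > 1e-6)
      bc_stop("image orientation varies across the series (offending file: ",
              s$path, ")")
  }
  ord <- order(vapply(slices, `[[`, numeric(1), "z"))
  slices <- slices[ord]
  zs <- vapply(slices, `[[`, numeric(1), "z")
  if (length(zs) > 1) {
    dz <- diff(zs)
    if (any(dz <= 0))
      bc_stop("duplicate slice positions in series (offending file: ",
              slices[[which(dz <= 0)[1] + 1]]$path, ")")
    if (max(dz) - min(dz) > 1e-3)
      bc_stop("irregular slice spacing in series (offending file: ",
              slices[[which.max(abs(dz - stats::median(dz))) + 1]]$path, ")")
    dzv <- mean(dz)
  } else {
    dzv <- NA_real_
    bc_stop("cannot determine slice spacing from a single-file series: ", path)
  }
  d1 <- dim(slices[[1]]$hu)
  vol <- array(0, c(length(slices), d1[1], d1[2]))
  for (i in seq_along(slices)) vol[i, , ] <- slices[[i]]$hu
  # PixelSpacing is (row spacing, column spacing) = (dy, dx)
  ct_volume(vol, spacing = c(dzv, ps[1], ps[2]),
            meta = list(orientation = slices[[1]]$orientation,
                        first_position = slices[[1]]$z))
}
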