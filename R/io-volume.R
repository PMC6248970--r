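#' Construct a volume + ROI pair
#'
#' Bundles a 3D scalar volume (Hounsfield-unit-like intensities) with an
#' aligned binary region-of-interest mask, the physical input of radiomic
#' feature extraction. Mask values other than 0/1 are coerced by
#' `value > 0`. Validation enforces identical dimensions and at least two
#' foreground voxels (texture features are undefined otherwise).
#'
#' @param volume 3D numeric array.
#' @param mask 3D array of the same dimensions; nonzero marks the ROI.
#' @param patient_id Opaque identifier string.
#' @param voxel_spacing Positive length-3 vector of voxel sizes in mm
#'   (informational only; extraction works on the voxel grid as given).
#' @return An object of class `volume_roi`: a list with elements `volume`,
#'   `mask` (integer 0/1), `patient_id`, `voxel_spacing`.
#' @examples
#' vol <- array(rnorm(64), c(4, 4, 4))
#' msk <- array(0L, c(4, 4, 4)); msk[2:3, 2:3, 2:3] <- 1L
#' roi <- volume_roi(vol, msk, "pt01")
#' sum(roi$mask)
#' @export
volume_roi <- function(volume, mask, patient_id = "unknown",
                       voxel_spacing = c(1, 1, 1)) {
  if (length(dim(volume)) != 3L) {
    abort("`volume` must be a 3D array.")
  }
  if (!identical(dim(volume), dim(mask))) {
    abort(sprintf(
      "volume and mask dimensions differ: %s vs %s",
      paste(dim(volume), collapse = "x"), paste(dim(mask), collapse = "x")
    ))
  }
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0)) {
    abort("`voxel_spacing` must be 3 positive lengths (mm).")
  }
  mask <- array(as.integer(mask > 0), dim = dim(mask))
  n_fg <- sum(mask)
  if (n_fg < 2L) {
    abort(sprintf(
      "ROI mask must contain at least 2 foreground voxels (found %d).", n_fg
    ))
  }
  structure(
    list(volume = volume, mask = mask,
         patient_id = as.character(patient_id),
         voxel_spacing = as.numeric(voxel_spacing)),
    class = "volume_roi"
  )
}

#' @export
print.volume_roi <- function(x, ...) {
  cat(sprintf(
    "<volume_roi> patient %s: %s volume, %d ROI voxels\n",
    x$patient_id, paste(dim(x$volume), collapse = "x"), sum(x$mask)
  ))
  invisible(x)
}

#' Read a volume and its ROI mask from disk
#'
#' Reads a 3D scalar volume and an aligned binary mask from NIfTI-1
#' (`.nii`, `.nii.gz`) or NRRD (`.nrrd`) files and returns a validated
#' [volume_roi()]. The two files may use different formats. DICOM series
#' assembly is out of scope; convert clinical series to NIfTI/NRRD first.
#'
#' @param volume_path,mask_path Paths to the volume and mask files.
#' @param patient_id Identifier attached to the result; defaults to the
#'   volume file name without extension.
#' @return A `volume_roi`.
#' @export
read_volume_roi <- function(volume_path, mask_path, patient_id = NULL) {
  v <- read_image3d(volume_path)
  m <- read_image3d(mask_path)
  if (is.null(patient_id)) {
    patient_id <- sub("\\.(nii(\\.gz)?|nrrd)$", "", basename(volume_path))
  }
  volume_roi(v$data, m$data, patient_id = patient_id,
             voxel_spacing = v$spacing)
}

# ---- NIfTI-1 and NRRD readers/writers -------------------------------------
# No NIfTI/NRRD package is available in this stack, so the two formats are
# implemented directly against their published layouts. Coverage is the
# subset the pipeline needs: single 3D scalar image, raw (optionally
# gzipped) little/big-endian data, common datatypes.

read_image3d <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    read_nifti(path)
  } else if (grepl("\\.nrrd$", path)) {
    read_nrrd(path)
  } else {
    abort(sprintf("Unsupported volume format (need .nii/.nii.gz/.nrrd): %s",
                  path))
  }
}

nifti_datatypes <- function() {
  # code -> list(what, size, signed)
  list(
    `2`   = list(what = "integer", size = 1L, signed = FALSE),
    `4`   = list(what = "integer", size = 2L, signed = TRUE),
    `8`   = list(what = "integer", size = 4L, signed = TRUE),
    `16`  = list(what = "numeric", size = 4L, signed = TRUE),
    `64`  = list(what = "numeric", size = 8L, signed = TRUE),
    `256` = list(what = "integer", size = 1L, signed = TRUE),
    `512` = list(what = "integer", size = 2L, signed = FALSE)
  )
}

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) abort(sprintf("Truncated NIfTI header: %s", path))
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = "little")
  endian <- "little"
  if (sz != 348L) {
    sz_big <- readBin(hdr[1:4], "integer", size = 4L, endian = "big")
    if (sz_big != 348L) abort(sprintf("Not a NIfTI-1 file: %s", path))
    endian <- "big"
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    abort(sprintf("Unsupported NIfTI magic '%s' in %s", magic, path))
  }
  rd_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                     n = n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "numeric",
                                     n = n, size = 4L, endian = endian)
  dim0 <- rd_i16(40, 8)
  ndim <- dim0[1]
  if (ndim < 3L) abort(sprintf("Expected a 3D NIfTI volume: %s", path))
  dims <- dim0[2:4]
  if (ndim > 3L && any(dim0[5:(ndim + 1)] > 1L)) {
    abort(sprintf("Expected a single 3D volume, got %dD: %s", ndim, path))
  }
  datatype <- rd_i16(70, 1)
  dt <- nifti_datatypes()[[as.character(datatype)]]
  if (is.null(dt)) {
    abort(sprintf("Unsupported NIfTI datatype code %d in %s", datatype, path))
  }
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  skip <- max(vox_offset, 348) - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  nvox <- prod(dims)
  data <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) < nvox) abort(sprintf("Truncated NIfTI data: %s", path))
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  spacing <- pixdim[2:4]
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  list(data = array(data, dim = dims), spacing = abs(spacing))
}

#' Write a 3D array as a NIfTI-1 file
#'
#' Writes single-file NIfTI-1 (`.nii`, gzipped if the path ends in `.gz`)
#' with float32 data and no spatial transform (qform/sform 0).
#'
#' @param x 3D numeric array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param spacing Voxel spacing in mm (length 3).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(x)) == 3L, length(spacing) == 3L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                       # sizeof_hdr
  w_raw(10); w_raw(18)             # data_type, db_name (unused)
  w_i32(0); w_i16(0); w_raw(2)     # extents, session_error, regular+dim_info
  w_i16(c(3, dim(x), 1, 1, 1, 1))  # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)      # intent_p1..p3, intent_code
  w_i16(16); w_i16(32); w_i16(0)   # datatype float32, bitpix, slice_start
  w_f32(c(1, spacing, 0, 0, 0, 0)) # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0); w_raw(1)               # slice_end, slice_code
  writeBin(as.raw(2L), con)        # xyzt_units = mm
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0, 0))                   # glmax, glmin
  w_raw(80); w_raw(24)             # descrip, aux_file
  w_i16(c(0, 0))                   # qform_code, sform_code
  w_f32(rep(0, 18))                # quatern/qoffset/srow
  w_raw(16)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4)                         # no extensions
  w_f32(as.vector(x))
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-9]$", magic)) {
    abort(sprintf("Not an NRRD file: %s", path))
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) abort(sprintf("NRRD header not terminated: %s", path))
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]] %||% "raw")
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (as.integer(fields[["dimension"]] %||% length(dims)) != 3L ||
      length(dims) != 3L) {
    abort(sprintf("Expected a 3D NRRD volume: %s", path))
  }
  spacing <- rep(1, 3)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  endian <- tolower(fields[["endian"]] %||% "little")
  type_map <- list(
    "uchar" = c("integer", 1, FALSE), "unsigned char" = c("integer", 1, FALSE),
    "uint8" = c("integer", 1, FALSE),
    "short" = c("integer", 2, TRUE), "int16" = c("integer", 2, TRUE),
    "ushort" = c("integer", 2, FALSE), "uint16" = c("integer", 2, FALSE),
    "int" = c("integer", 4, TRUE), "int32" = c("integer", 4, TRUE),
    "float" = c("numeric", 4, TRUE),
    "double" = c("numeric", 8, TRUE)
  )
  tm <- type_map[[tolower(type)]]
  if (is.null(tm)) abort(sprintf("Unsupported NRRD type '%s' in %s", type, path))
  nvox <- prod(dims)
  if (enc == "raw") {
    data <- readBin(con, tm[[1]], n = nvox, size = as.integer(tm[[2]]),
                    signed = as.logical(tm[[3]]), endian = endian)
  } else if (enc %in% c("ascii", "text", "txt")) {
    data <- scan(con, what = double(), n = nvox, quiet = TRUE)
  } else {
    abort(sprintf("Unsupported NRRD encoding '%s' in %s", enc, path))
  }
  if (length(data) < nvox) abort(sprintf("Truncated NRRD data: %s", path))
  list(data = array(as.numeric(data), dim = dims), spacing = abs(spacing))
}

#' Write a 3D array as an NRRD file
#'
#' Raw little-endian float encoding, 3D, with per-axis spacings.
#'
#' @inheritParams write_nifti
#' @param path Output path ending in `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(x)) == 3L, length(spacing) == 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "NRRD0004\n",
    "type: float\n",
    "dimension: 3\n",
    "sizes: ", paste(dim(x), collapse = " "), "\n",
    "encoding: raw\n",
    "endian: little\n",
    "spacings: ", paste(format(spacing, trim = TRUE), collapse = " "), "\n",
    "\n"
  )
  writeBin(charToRaw(hdr), con)
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
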