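#' In-ROI intensities
#'
#' Returns the raw intensity of every foreground voxel, ordered by
#' lexicographic voxel index (column-major array order). First-order
#' statistics are computed on these raw values; texture features work on
#' the quantized levels from [quantize_roi()].
#'
#' @param roi A [volume_roi()].
#' @return Numeric vector, one value per mask-foreground voxel.
#' @export
roi_intensities <- function(roi) {
  stopifnot(inherits(roi, "volume_roi"))
  roi$volume[roi$mask == 1L]
}

#' Quantize ROI intensities to G gray levels
#'
#' Equal-width binning of the ROI's own intensity range into `G` levels:
#' `level(v) = min(G, 1 + floor(G * (v - min) / (max - min)))`. Voxels
#' outside the ROI get level 0; a constant ROI maps entirely to level 1.
#' This gray-level alphabet feeds both the co-occurrence matrices and the
#' LBP-TOP codes.
#'
#' @param roi A [volume_roi()].
#' @param G Number of gray levels (>= 2).
#' @return An object of class `quantized_roi`: list with `levels` (integer
#'   array, 0 outside ROI), `G`, `roi_min`, `roi_max`, and the source
#'   `roi`.
#' @examples
#' vol <- array(seq(0, 63), c(4, 4, 4))
#' msk <- array(1L, c(4, 4, 4))
#' q <- quantize_roi(volume_roi(vol, msk), G = 4)
#' table(q$levels)
#' @export
quantize_roi <- function(roi, G = 32L) {
  stopifnot(inherits(roi, "volume_roi"))
  if (G < 2) abort("`G` must be at least 2.")
  G <- as.integer(G)
  vals <- roi$volume
  fg <- roi$mask == 1L
  rmin <- min(vals[fg])
  rmax <- max(vals[fg])
  lev <- array(0L, dim = dim(vals))
  if (rmax == rmin) {
    lev[fg] <- 1L
  } else {
    lev[fg] <- pmin(G, 1L + as.integer(floor(G * (vals[fg] - rmin) / (rmax - rmin))))
  }
  structure(
    list(levels = lev, G = G, roi_min = rmin, roi_max = rmax, source = roi),
    class = "quantized_roi"
  )
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> G=%d levels over [%g, %g], %d ROI voxels\n",
              x$G, x$roi_min, x$roi_max, sum(x$levels > 0L)))
  invisible(x)
}
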