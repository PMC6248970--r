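#' Normalized first-order intensity histogram
#'
#' Equal-width histogram of raw in-ROI intensities over `[min, max]` with
#' `n_bins` bins; a constant input collapses to a single bin carrying all
#' mass. Probabilities sum to one.
#'
#' @param intensities Numeric vector, at least 2 values.
#' @param n_bins Number of bins.
#' @return A list with `centers` (bin centers) and `p` (probabilities).
#' @export
firstorder_histogram <- function(intensities, n_bins = 64L) {
  if (length(intensities) < 2L) {
    abort("Need at least 2 intensity values for a histogram.")
  }
  if (n_bins < 1L) abort("`n_bins` must be positive.")
  lo <- min(intensities)
  hi <- max(intensities)
  if (hi == lo) {
    return(list(centers = lo, p = 1))
  }
  idx <- pmin(n_bins, 1L + floor(n_bins * (intensities - lo) / (hi - lo)))
  counts <- tabulate(idx, nbins = n_bins)
  w <- (hi - lo) / n_bins
  list(centers = lo + (seq_len(n_bins) - 0.5) * w,
       p = counts / length(intensities))
}

#' The 12 first-order statistical features
#'
#' Computes the first-order family of the 251-feature inventory: the four
#' moments of the raw intensity distribution (mean, population standard
#' deviation, skewness `m3/m2^1.5`, raw kurtosis `m4/m2^2`, Gaussian -> 3)
#' plus eight histogram-shape descriptors: the histogram width (span of
#' occupied bin centers), energy `sum(p^2)`, Shannon entropy in bits, the
#' absolute-maximum probability and its bin center, the energy in the
#' +-2-bin window around that maximum, the number of relative maxima
#' (strict local peaks; a flat plateau higher than its surroundings counts
#' once, at its left edge), and the summed squared probability of those
#' peaks.
#'
#' A constant input is degenerate: skewness and kurtosis are reported as 0
#' and width as 0, with a single-bin histogram (entropy 0, energy 1).
#'
#' @inheritParams firstorder_histogram
#' @return A named numeric vector of 12 values, names `stat_mean` ...
#'   `stat_energyRelMax`, in registry order.
#' @examples
#' x <- rnorm(1000)
#' firstorder_features(x)[c("stat_entropy", "stat_numMaxRel")]
#' @export
firstorder_features <- function(intensities, n_bins = 64L) {
  if (length(intensities) < 2L) {
    abort("Need at least 2 intensity values.")
  }
  n <- length(intensities)
  mu <- mean(intensities)
  m2 <- mean((intensities - mu)^2)
  m3 <- mean((intensities - mu)^3)
  m4 <- mean((intensities - mu)^4)
  if (m2 > 0) {
    stdev <- sqrt(m2)
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  } else {
    stdev <- 0
    skew <- 0   # degenerate constant input
    kurt <- 0
  }

  h <- firstorder_histogram(intensities, n_bins)
  p <- h$p
  centers <- h$centers
  occ <- which(p > 0)
  width <- centers[max(occ)] - centers[min(occ)]
  energy <- sum(p^2)
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  imax <- which.max(p)       # ties -> lowest center
  max_val <- p[imax]
  max_pos <- centers[imax]
  around <- seq(max(1L, imax - 2L), min(length(p), imax + 2L))
  energy_around <- sum(p[around]^2)
  peaks <- relative_maxima(p)
  num_max_rel <- length(peaks)
  energy_rel <- sum(p[peaks]^2)

  out <- c(mu, stdev, skew, kurt, width, energy, entropy, max_val, max_pos,
           energy_around, num_max_rel, energy_rel)
  names(out) <- paste0("stat_", firstorder_stat_names())
  out
}

# Strict local maxima of a nonnegative sequence; a plateau (run of equal
# values) higher than both flanking runs counts once, at its left edge.
# Boundary runs compare against their single neighbor.
relative_maxima <- function(p) {
  stopifnot(length(p) >= 1L)
  r <- rle(p)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_max <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1L || r$values[i] > r$values[i - 1L]
    right_ok <- i == k || r$values[i] > r$values[i + 1L]
    left_ok && right_ok
  }, logical(1))
  starts[is_max & r$values > 0]
}
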