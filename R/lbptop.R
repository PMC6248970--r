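#' LBP code-compression mapping tables
#'
#' Local binary patterns with P = 8 neighbors produce 256 raw codes;
#' standard mappings compress them: `u2` keeps the 58 uniform patterns (at
#' most 2 circular 0/1 transitions) in individual bins plus one catch-all
#' (59 bins); `ri` merges bitwise rotations, keeping the minimum rotation
#' as canonical (36 binary necklaces); `riu2` combines both (10 bins:
#' uniform patterns by their number of set bits, plus a catch-all);
#' `basic` is the identity (256 bins).
#'
#' @param mapping One of `"basic"`, `"u2"`, `"ri"`, `"riu2"`.
#' @param P Neighbor count; only 8 is supported.
#' @return Integer vector of length 256 assigning each raw code a 1-based
#'   bin index; the number of bins is `max()` of the table.
#' @examples
#' max(lbp_mapping_table("u2"))   # 59
#' max(lbp_mapping_table("ri"))   # 36
#' max(lbp_mapping_table("riu2")) # 10
#' @export
lbp_mapping_table <- function(mapping = c("basic", "u2", "ri", "riu2"), P = 8L) {
  mapping <- match.arg(mapping)
  if (P != 8L) abort("Only P = 8 neighbors are supported.")
  codes <- 0:255
  bits <- t(vapply(codes, function(cd) as.integer(bitwAnd(bitwShiftR(cd, 0:7), 1L)),
                   integer(8)))
  transitions <- rowSums(bits != bits[, c(2:8, 1)])
  nbits <- rowSums(bits)
  uniform <- transitions <= 2L
  switch(mapping,
    basic = codes + 1L,
    u2 = {
      tab <- integer(256)
      tab[uniform] <- seq_len(sum(uniform))
      tab[!uniform] <- sum(uniform) + 1L
      tab
    },
    ri = {
      canon <- vapply(codes, function(cd) {
        min(vapply(0:7, function(r) rotate_code8(cd, r), integer(1)))
      }, integer(1))
      match(canon, sort(unique(canon)))
    },
    riu2 = {
      tab <- integer(256)
      tab[uniform] <- nbits[uniform] + 1L
      tab[!uniform] <- 10L
      tab
    }
  )
}

# circular rotation of an 8-bit code by r positions
rotate_code8 <- function(code, r) {
  bitwAnd(bitwOr(bitwShiftR(code, r), bitwShiftL(code, 8L - r)), 255L)
}

#' The 10 LBP-TOP pattern configurations
#'
#' The textural inventory uses 10 configurations -- radii 1..3 crossed with
#' the `basic`, `u2` and `ri` mappings, plus `riu2` at radius 3 -- each
#' summarized by 10 distribution statistics, giving the 100 LBP-TOP
#' features of the registry.
#'
#' @param radii Radii to include (subset of 1:3; the `riu2` configuration
#'   is included only when radius 3 is).
#' @return List of configuration lists with elements `R`, `mapping`,
#'   `bins_per_plane`.
#' @export
lbp_configs <- function(radii = c(1L, 2L, 3L)) {
  bins <- c(basic = 256L, u2 = 59L, ri = 36L, riu2 = 10L)
  cfgs <- list()
  for (R in sort(unique(as.integer(radii)))) {
    for (mp in c("basic", "u2", "ri")) {
      cfgs[[length(cfgs) + 1L]] <- list(R = R, mapping = mp,
                                        bins_per_plane = unname(bins[mp]))
    }
    if (R == 3L) {
      cfgs[[length(cfgs) + 1L]] <- list(R = 3L, mapping = "riu2",
                                        bins_per_plane = unname(bins["riu2"]))
    }
  }
  cfgs
}

# Feature-name suffix: LBP<R> for basic, LBP<R>_u / _ri / _riu2 otherwise.
lbp_config_tag <- function(cfg) {
  suffix <- switch(cfg$mapping, basic = "", u2 = "_u", ri = "_ri",
                   riu2 = "_riu2")
  paste0("LBP", cfg$R, suffix)
}

# Sampling offsets of the 8 neighbors at radius R: angle 2*pi*k/8,
# offsets (R cos, R sin), with values within 1e-9 of an integer snapped to
# it so that axis-aligned neighbors are sampled exactly.
lbp_offsets <- function(R) {
  k <- 0:7
  du <- R * cos(2 * pi * k / 8)
  dv <- R * sin(2 * pi * k / 8)
  snap <- function(x) ifelse(abs(x - round(x)) < 1e-9, round(x), x)
  cbind(du = snap(du), dv = snap(dv))
}

#' LBP code of one pixel in a 2D plane
#'
#' Compares the center pixel against 8 neighbors sampled on a circle of
#' radius `R` (angle `2*pi*k/8`, bilinear interpolation); bit k is set iff
#' the neighbor value is greater than or equal to the center, with ties
#' decided at tolerance 1e-9: interpolated values within 1e-9 of the
#' center count as equal, so that exact real-arithmetic ties (common on
#' quantized levels) are not flipped by floating-point rounding. The
#' caller must ensure the circle lies inside the plane bounds.
#'
#' @param plane 2D numeric matrix.
#' @param center Integer pair `(row, col)`.
#' @param R Sampling radius.
#' @return Integer code in 0..255.
#' @examples
#' m <- matrix(5, 7, 7)
#' lbp_code(m, c(4, 4), 1)  # constant plane -> all bits set -> 255
#' @export
lbp_code <- function(plane, center, R = 1L) {
  stopifnot(is.matrix(plane), length(center) == 2L)
  u <- center[1]
  v <- center[2]
  if (u - R < 1 || u + R > nrow(plane) || v - R < 1 || v + R > ncol(plane)) {
    abort("Sampling circle does not fit inside the plane bounds.")
  }
  offs <- lbp_offsets(R)
  cval <- plane[u, v]
  code <- 0L
  for (k in 1:8) {
    nu <- u + offs[k, 1]
    nv <- v + offs[k, 2]
    nval <- bilinear2d(plane, nu, nv)
    if (nval >= cval - 1e-9) code <- code + bitwShiftL(1L, k - 1L)
  }
  code
}

bilinear2d <- function(plane, u, v) {
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  u1 <- if (fu > 0) u0 + 1 else u0
  v1 <- if (fv > 0) v0 + 1 else v0
  (1 - fu) * (1 - fv) * plane[u0, v0] +
    fu * (1 - fv) * plane[u1, v0] +
    (1 - fu) * fv * plane[u0, v1] +
    fu * fv * plane[u1, v1]
}

# Raw LBP codes for all valid in-ROI voxels in one orthogonal plane.
# axes: integer pair, e.g. c(1, 2) for the XY plane. Codes are computed on
# the quantized level array (zeros outside the ROI are sampled as stored).
lbp_plane_codes <- function(levels, roi_coords, axes, R) {
  dims <- dim(levels)
  a <- axes[1]; b <- axes[2]
  ca <- roi_coords[, a]
  cb <- roi_coords[, b]
  valid <- ca - R >= 1 & ca + R <= dims[a] & cb - R >= 1 & cb + R <= dims[b]
  if (!any(valid)) return(integer(0))
  pts <- roi_coords[valid, , drop = FALSE]
  n <- nrow(pts)
  center <- levels[pts]
  offs <- lbp_offsets(R)
  code <- integer(n)
  for (k in 1:8) {
    du <- offs[k, 1]; dv <- offs[k, 2]
    u <- pts[, a] + du
    v <- pts[, b] + dv
    u0 <- floor(u); v0 <- floor(v)
    fu <- u - u0; fv <- v - v0
    u1 <- ifelse(fu > 0, u0 + 1, u0)
    v1 <- ifelse(fv > 0, v0 + 1, v0)
    corner <- function(ui, vi) {
      idx <- pts
      idx[, a] <- ui
      idx[, b] <- vi
      levels[idx]
    }
    nval <- (1 - fu) * (1 - fv) * corner(u0, v0) +
      fu * (1 - fv) * corner(u1, v0) +
      (1 - fu) * fv * corner(u0, v1) +
      fu * fv * corner(u1, v1)
    code <- code + bitwShiftL(1L, k - 1L) * as.integer(nval >= center - 1e-9)
  }
  code
}

#' LBP-TOP histogram of a quantized ROI
#'
#' For every in-ROI voxel whose sampling circle of radius `R` fits inside
#' the volume bounds in a given orthogonal plane, the LBP code is computed
#' in that plane on the quantized levels; the three per-plane histograms
#' (plane order XY, XZ, YZ) are compressed through the configuration's
#' mapping table, each normalized to total 1/3, and concatenated, so the
#' full histogram sums to 1. If no voxel admits a full circle in some
#' plane the histogram is degenerate (flagged; downstream statistics 0).
#'
#' @param q A [quantize_roi()] result.
#' @param config One element of [lbp_configs()].
#' @return A list of class `lbp_histogram`: `h` (length `3 *
#'   bins_per_plane`), `config`, `sample_count` (total coded voxels).
#' @export
lbp_top_histogram <- function(q, config) {
  stopifnot(inherits(q, "quantized_roi"))
  lev <- q$levels
  roi_coords <- which(lev > 0L, arr.ind = TRUE)
  tab <- lbp_mapping_table(config$mapping)
  nb <- config$bins_per_plane
  planes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  h <- numeric(0)
  total <- 0L
  degenerate <- FALSE
  for (ax in planes) {
    codes <- lbp_plane_codes(lev, roi_coords, ax, config$R)
    hp <- numeric(nb)
    if (length(codes) > 0L) {
      raw <- tabulate(codes + 1L, nbins = 256L)
      hp <- as.numeric(rowsum(raw, tab)[, 1]) / length(codes) / 3
      total <- total + length(codes)
    } else {
      degenerate <- TRUE
    }
    h <- c(h, hp)
  }
  structure(list(h = h, config = config, sample_count = total,
                 degenerate = degenerate),
            class = "lbp_histogram")
}

#' The 10 distribution statistics of an LBP-TOP histogram
#'
#' Treats the concatenated histogram `h` as a distribution over its 1-based
#' bin positions `i`: mean `sum(i h_i)`, population SD, skewness and raw
#' kurtosis (conventions as in [firstorder_features()]); range = number of
#' occupied bins (pattern diversity); energy `sum(h^2)`; entropy in bits;
#' the maximum probability and its position (ties to the lowest bin); and
#' the count of strict relative maxima. A degenerate (zero or incomplete)
#' histogram yields all zeros with a `degenerate` attribute.
#'
#' @param hist An `lbp_histogram`.
#' @return Named numeric vector of 10 statistics.
#' @export
lbp_summary <- function(hist) {
  stopifnot(inherits(hist, "lbp_histogram"))
  h <- hist$h
  out <- stats::setNames(numeric(10), lbp_stat_names())
  if (hist$sample_count == 0L || isTRUE(hist$degenerate) || sum(h) == 0) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  i <- seq_along(h)
  mu <- sum(i * h)
  m2 <- sum((i - mu)^2 * h)
  m3 <- sum((i - mu)^3 * h)
  m4 <- sum((i - mu)^4 * h)
  out["mean"] <- mu
  out["std"] <- sqrt(m2)
  out["skewness"] <- if (m2 > 0) m3 / m2^1.5 else 0
  out["kurtosis"] <- if (m2 > 0) m4 / m2^2 else 0
  out["range"] <- sum(h > 0)
  out["energy"] <- sum(h^2)
  out["entropy"] <- -sum(h[h > 0] * log2(h[h > 0]))
  out["maxVal"] <- max(h)
  out["argmax"] <- which.max(h)
  out["numMaxRel"] <- length(relative_maxima(h))
  out
}

#' All 100 LBP-TOP features of a quantized ROI
#'
#' 10 statistics for each of the 10 configurations, named
#' `lbp_<stat>_LBP<R>[_<mapping>]` in registry order.
#'
#' @param q A [quantize_roi()] result.
#' @param radii Radii passed to [lbp_configs()].
#' @return Named numeric vector of length 100 (for the default radii).
#' @export
lbptop_features <- function(q, radii = c(1L, 2L, 3L)) {
  cfgs <- lbp_configs(radii)
  out <- unlist(lapply(cfgs, function(cfg) {
    v <- lbp_summary(lbp_top_histogram(q, cfg))
    names(v) <- paste0("lbp_", lbp_stat_names(), "_", lbp_config_tag(cfg))
    v
  }))
  out
}
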