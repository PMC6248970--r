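#' Canonical 3D co-occurrence directions
#'
#' The 26 unit-offset neighbors of a voxel fall into 13 +/- equivalence
#' classes; opposite displacements yield transposed co-occurrence matrices
#' and identical values for every statistic used here, so one
#' representative per class is kept. The canonical representative of
#' `{d, -d}` is the member whose last nonzero component is negative (this
#' reproduces the direction names of the published signature, e.g.
#' `(0,-1,0)` and `(-1,1,-1)`); the list is ordered lexicographically.
#'
#' @return A list of 13 integer 3-vectors.
#' @export
glcm_directions <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  keep <- apply(offs, 1, function(d) {
    nz <- d[d != 0]
    nz[length(nz)] < 0
  })
  offs <- offs[keep, ]
  offs <- offs[order(offs$dx, offs$dy, offs$dz), ]
  unname(lapply(seq_len(nrow(offs)), function(i) as.integer(offs[i, ])))
}

#' Gray-level co-occurrence matrix along one displacement
#'
#' Counts ordered voxel pairs `(v, v + d)` whose levels co-occur, requiring
#' both voxels to lie inside the ROI, and normalizes by the pair count. The
#' matrix is unsymmetrized: no transpose accumulation, so `glcm(q, -d)` is
#' exactly the transpose of `glcm(q, d)`.
#'
#' @param q A [quantize_roi()] result.
#' @param d Integer displacement 3-vector with components in -1:1, not all
#'   zero.
#' @return A list of class `glcm_matrix`: `P` (G x G probability matrix),
#'   `direction`, `pair_count`. If the ROI is too thin along `d` to admit
#'   any pair, `P` is all zeros and `pair_count` 0; downstream statistics
#'   then return 0 with a degeneracy flag.
#' @examples
#' vol <- array(rep(c(0, 1), 32), c(4, 4, 4))
#' q <- quantize_roi(volume_roi(vol, array(1, c(4, 4, 4))), G = 2)
#' glcm(q, c(1L, 0L, 0L))$P
#' @export
glcm <- function(q, d) {
  stopifnot(inherits(q, "quantized_roi"))
  d <- as.integer(d)
  if (length(d) != 3L || any(abs(d) > 1L) || all(d == 0L)) {
    abort("`d` must be a nonzero 3-vector with components in -1:1.")
  }
  lev <- q$levels
  dims <- dim(lev)
  src <- lapply(1:3, function(a) {
    seq_len(max(0L, dims[a] - abs(d[a]))) + max(0L, -d[a])
  })
  a <- lev[src[[1]], src[[2]], src[[3]], drop = FALSE]
  b <- lev[src[[1]] + d[1], src[[2]] + d[2], src[[3]] + d[3], drop = FALSE]
  ok <- a > 0L & b > 0L
  G <- q$G
  P <- matrix(0, G, G)
  npair <- sum(ok)
  if (npair > 0) {
    counts <- tabulate((a[ok] - 1L) * G + b[ok], nbins = G * G)
    P <- matrix(counts, G, G, byrow = TRUE) / npair
  }
  structure(list(P = P, direction = d, pair_count = npair),
            class = "glcm_matrix")
}

#' The 10 co-occurrence statistics
#'
#' With `p = P(i, j)` over levels `i, j` and marginal means/SDs `mu_x,
#' mu_y, sigma_x, sigma_y`:
#' energy `sum p^2`; entropy `-sum p log2 p`; inertia (contrast)
#' `sum (i-j)^2 p`; absolute (dissimilarity) `sum |i-j| p`; idm (inverse
#' difference moment) `sum p / (1 + (i-j)^2)`; correlation
#' `sum (i-mu_x)(j-mu_y) p / (sigma_x sigma_y)` (0 if either sigma is 0);
#' sumAverage `sum_s s p_{x+y}(s)`; variance as the symmetrized marginal
#' variance `(sigma_x^2 + sigma_y^2) / 2` (symmetrized so that every
#' statistic is invariant under direction reversal -- see Details);
#' clusterShade `sum (i+j-mu_x-mu_y)^3 p`; clusterProminence the same with
#' fourth power. A zero matrix yields all zeros and a `degenerate`
#' attribute.
#'
#' @details Only one representative of each `{d, -d}` direction pair is
#' kept (see [glcm_directions()]), which is sound only if every statistic
#' takes the same value on a matrix and its transpose. That holds for nine
#' of the ten statistics as usually written; the marginal variance
#' `sum (i-mu_x)^2 p` is the exception, so it is symmetrized to the mean
#' of the two marginal variances, which coincides with it whenever the
#' matrix is symmetric.
#'
#' @param M A `glcm_matrix`.
#' @return Named numeric vector of 10 statistics (names as in
#'   [glcm_stat_names()]).
#' @export
glcm_stats <- function(M) {
  stopifnot(inherits(M, "glcm_matrix"))
  P <- M$P
  G <- nrow(P)
  out <- stats::setNames(numeric(10), glcm_stat_names())
  if (M$pair_count == 0 || sum(P) == 0) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(G) * px)
  muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))
  dif <- i - j
  s <- i + j - mux - muy
  out["energy"] <- sum(P^2)
  out["entropy"] <- -sum(P[P > 0] * log2(P[P > 0]))
  out["inertia"] <- sum(dif^2 * P)
  out["absolute"] <- sum(abs(dif) * P)
  out["idm"] <- sum(P / (1 + dif^2))
  out["correlation"] <- if (sx > 0 && sy > 0) {
    sum((i - mux) * (j - muy) * P) / (sx * sy)
  } else 0
  out["sumAverage"] <- sum((i + j) * P)
  out["variance"] <- (sx^2 + sy^2) / 2
  out["clusterShade"] <- sum(s^3 * P)
  out["clusterProminence"] <- sum(s^4 * P)
  out
}

#' All 130 co-occurrence features of a quantized ROI
#'
#' 10 statistics for each of the 13 canonical directions, named
#' `glcm_<stat>_<dx>,<dy>,<dz>` in registry order (statistic-major).
#'
#' @param q A [quantize_roi()] result.
#' @return Named numeric vector of length 130.
#' @export
glcm_features <- function(q) {
  dirs <- glcm_directions()
  stats_by_dir <- lapply(dirs, function(d) glcm_stats(glcm(q, d)))
  tags <- vapply(dirs, function(d) paste(d, collapse = ","), character(1))
  out <- numeric(0)
  for (s in seq_along(glcm_stat_names())) {
    v <- vapply(stats_by_dir, `[[`, numeric(1), s)
    names(v) <- paste0("glcm_", glcm_stat_names()[s], "_", tags)
    out <- c(out, v)
  }
  out
}
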