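# Shared fixture builders and independent oracles. The oracles are
# deliberately naive re-implementations (per-pair enumeration, per-pixel
# loops, direct formula evaluation) kept separate from the package's
# computation paths.

# Small deterministic ROI: dims d, intensities from a seeded normal, full
# or ellipsoidal mask.
tiny_roi <- function(d = c(5, 5, 5), seed = 1, full_mask = TRUE) {
  withr::with_seed(seed, {
    vol <- array(rnorm(prod(d), 0, 10), d)
    msk <- if (full_mask) array(1L, d) else {
      ctr <- (d + 1) / 2
      g <- lapply(seq_along(d), seq_len)
      dist2 <- outer(outer((g[[1]] - ctr[1])^2, (g[[2]] - ctr[2])^2, "+"),
                     (g[[3]] - ctr[3])^2, "+")
      array(as.integer(dist2 <= (min(d) / 2)^2), d)
    }
    volume_roi(vol, msk, "tiny")
  })
}

# Random quantized ROI for property tests.
random_qroi <- function(d = c(6, 6, 6), G = 4, seed = 1, p_roi = 0.8) {
  withr::with_seed(seed, {
    vol <- array(runif(prod(d), 0, 100), d)
    msk <- array(as.integer(runif(prod(d)) < p_roi), d)
    while (sum(msk) < 2) msk[sample(length(msk), 2)] <- 1L
    quantize_roi(volume_roi(vol, msk), G)
  })
}

# --- GLCM oracle: exhaustive per-voxel pair enumeration --------------------
oracle_glcm <- function(q, d) {
  lev <- q$levels
  dims <- dim(lev)
  G <- q$G
  counts <- matrix(0, G, G)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    x2 <- x + d[1]; y2 <- y + d[2]; z2 <- z + d[3]
    if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2] ||
        z2 < 1 || z2 > dims[3]) next
    a <- lev[x, y, z]; b <- lev[x2, y2, z2]
    if (a > 0 && b > 0) counts[a, b] <- counts[a, b] + 1
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

# --- LBP oracle: per-pixel, per-angle interpolation ------------------------
# Independent of the package path: loops over angles, interpolates from the
# four surrounding pixels directly. Shares only the stated sampling
# convention (angle 2*pi*k/8, offsets snapped to integers within 1e-9).
oracle_lbp_code <- function(plane, u, v, R) {
  cval <- plane[u, v]
  code <- 0
  for (k in 0:7) {
    ang <- 2 * pi * k / 8
    du <- R * cos(ang); dv <- R * sin(ang)
    if (abs(du - round(du)) < 1e-9) du <- round(du)
    if (abs(dv - round(dv)) < 1e-9) dv <- round(dv)
    x <- u + du; y <- v + dv
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    val <- 0
    for (cx in 0:1) for (cy in 0:1) {
      wx <- if (cx == 0) 1 - fx else fx
      wy <- if (cy == 0) 1 - fy else fy
      if (wx == 0 || wy == 0) next
      val <- val + wx * wy * plane[x0 + cx, y0 + cy]
    }
    if (val >= cval - 1e-9) code <- code + 2^k  # shared tie tolerance
  }
  code
}

# Full LBP-TOP histogram oracle: per-voxel loops over the three planes.
oracle_lbp_top <- function(q, cfg) {
  lev <- q$levels
  dims <- dim(lev)
  tab <- lbp_mapping_table(cfg$mapping)
  planes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  h <- numeric(0)
  for (ax in planes) {
    counts <- numeric(cfg$bins_per_plane)
    ncodes <- 0
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
      if (lev[x, y, z] == 0L) next
      co <- c(x, y, z)
      a <- co[ax[1]]; b <- co[ax[2]]
      if (a - cfg$R < 1 || a + cfg$R > dims[ax[1]] ||
          b - cfg$R < 1 || b + cfg$R > dims[ax[2]]) next
      # extract the 2D plane through this voxel
      keep <- setdiff(1:3, ax)
      pl <- switch(keep,
                   `1` = lev[co[1], , ],
                   `2` = lev[, co[2], ],
                   `3` = lev[, , co[3]])
      code <- oracle_lbp_code(pl, a, b, cfg$R)
      counts[tab[code + 1]] <- counts[tab[code + 1]] + 1
      ncodes <- ncodes + 1
    }
    if (ncodes > 0) counts <- counts / ncodes / 3
    h <- c(h, counts)
  }
  h
}

# --- .632+ formula oracle: direct transcription of the estimator -----------
oracle_632plus <- function(err_bar, eps0, gamma) {
  eps0p <- min(eps0, gamma)
  R <- 0
  if (gamma > err_bar && eps0 > err_bar) {
    R <- (eps0 - err_bar) / (gamma - err_bar)
  }
  R <- max(0, min(1, R))
  w <- 0.632 / (1 - 0.368 * R)
  (1 - w) * err_bar + w * eps0p
}

# Small labelled table with one planted feature, for selection tests.
toy_table <- function(n = 24, p = 6, d = 3, seed = 1) {
  g <- generate_feature_table(n = n, p = p, k_informative = 1, d = d,
                              seed = seed)
  g
}
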