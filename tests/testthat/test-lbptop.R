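test_that("mapping tables have the combinatorial bin counts", {
  expect_equal(max(lbp_mapping_table("u2")), 59)    # P(P-1)+2 uniform + 1
  expect_equal(max(lbp_mapping_table("ri")), 36)    # 8-bit binary necklaces
  expect_equal(max(lbp_mapping_table("riu2")), 10)  # P + 2
  expect_equal(lbp_mapping_table("basic"), 1:256)
  # every bin is reachable
  for (mp in c("u2", "ri", "riu2")) {
    tab <- lbp_mapping_table(mp)
    expect_setequal(unique(tab), seq_len(max(tab)))
  }
  # rotation invariance of the ri table: rotated codes share a bin
  tab <- lbp_mapping_table("ri")
  rot <- function(code, r) bitwAnd(bitwOr(bitwShiftR(code, r),
                                          bitwShiftL(code, 8 - r)), 255)
  for (code in c(1, 3, 7, 45, 170, 201)) {
    expect_equal(unique(tab[vapply(0:7, rot, integer(1), code = code) + 1]),
                 tab[code + 1])
  }
})

test_that("single-pixel codes follow the >= comparison convention", {
  m <- matrix(5, 7, 7)
  expect_equal(lbp_code(m, c(4, 4), 1), 255)  # constant plane: all ties set
  expect_equal(lbp_code(m, c(4, 4), 3), 255)

  m2 <- matrix(1, 7, 7); m2[4, 4] <- 9
  expect_equal(lbp_code(m2, c(4, 4), 1), 0)   # center strictly above all

  expect_error(lbp_code(m, c(1, 4), 1), "bounds")
})

test_that("codes on a step edge match the per-angle interpolation oracle", {
  # vertical step: bright half-plane on the high-column side
  m <- matrix(0, 13, 13); m[, 8:13] <- 10
  for (R in 1:3) {
    for (ctr in list(c(7, 7), c(7, 9), c(5, 8))) {
      expect_equal(lbp_code(m, ctr, R),
                   oracle_lbp_code(m, ctr[1], ctr[2], R))
    }
  }
  # on an axis-aligned intensity ramp the bits split by direction: the 3
  # neighbors sampling the brighter side are set, the 3 darker ones are
  # not, and the 2 edge-parallel neighbors tie (set under >=)
  ramp <- matrix(rep(1:13, each = 13), 13, 13)  # value = column index
  for (R in 1:3) {
    code <- lbp_code(ramp, c(7, 7), R)
    expect_equal(code, oracle_lbp_code(ramp, 7, 7, R))
    bits <- as.integer(intToBits(code))[1:8]
    offs <- radsig:::lbp_offsets(R)
    expect_true(all(bits[offs[, "dv"] > 0.1] == 1))   # brighter side
    expect_true(all(bits[offs[, "dv"] < -0.1] == 0))  # darker side
    expect_true(all(bits[abs(offs[, "dv"]) < 0.1] == 1))  # ties
  }
})

test_that("LBP-TOP histograms match the exhaustive per-voxel oracle", {
  for (seed in 1:2) {
    q <- random_qroi(d = c(8, 8, 8), G = 6, seed = seed, p_roi = 1)
    for (cfg in lbp_configs()) {
      h <- lbp_top_histogram(q, cfg)
      expect_equal(h$h, oracle_lbp_top(q, cfg), tolerance = 1e-12,
                   info = lbp_config_tag(cfg))
      expect_equal(sum(h$h), 1, tolerance = 1e-12)
    }
  }
  # and on a partially masked alternating-slab texture
  vol <- array(rep(c(0, 50), each = 64), c(8, 4, 4))
  msk <- array(1, c(8, 4, 4)); msk[1, , ] <- 0
  q2 <- quantize_roi(volume_roi(vol, msk), 4)
  for (cfg in lbp_configs(radii = 1L)) {
    expect_equal(lbp_top_histogram(q2, cfg)$h, oracle_lbp_top(q2, cfg),
                 tolerance = 1e-12)
  }
})

test_that("a constant ROI concentrates each plane's mass in one bin", {
  q <- quantize_roi(volume_roi(array(3, c(7, 7, 7)), array(1, c(7, 7, 7))), 8)
  for (cfg in lbp_configs()) {
    h <- lbp_top_histogram(q, cfg)
    expect_equal(sum(h$h > 0), 3)         # one occupied bin per plane
    expect_equal(sum(h$h), 1, tolerance = 1e-12)
    s <- lbp_summary(h)
    expect_equal(unname(s["range"]), 3)
  }
})

test_that("ri histograms are invariant under 90-degree plane rotation", {
  withr::with_seed(9, base <- matrix(sample(1:4, 49, TRUE), 7, 7))
  vol <- array(0, c(7, 7, 3))
  for (z in 1:3) vol[, , z] <- base
  vol_rot <- array(0, c(7, 7, 3))
  for (z in 1:3) vol_rot[, , z] <- t(base)[, 7:1]   # 90-degree rotation
  # restrict coding to the XY plane by masking only the middle slice
  msk <- array(0, c(7, 7, 3)); msk[, , 2] <- 1
  q1 <- quantize_roi(volume_roi(vol, msk), 4)
  q2 <- quantize_roi(volume_roi(vol_rot, msk), 4)
  cfg <- lbp_configs(radii = 1L)[[3]]  # R = 1, ri mapping
  expect_identical(cfg$mapping, "ri")
  h1 <- lbp_top_histogram(q1, cfg)$h[1:36]          # XY block
  h2 <- lbp_top_histogram(q2, cfg)$h[1:36]
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("summary statistics match direct formula evaluation", {
  h6 <- c(0.5, 0, 0.25, 0, 0.125, 0.125)
  hist <- structure(list(h = h6, config = lbp_configs(1L)[[1]],
                         sample_count = 8L, degenerate = FALSE),
                    class = "lbp_histogram")
  s <- lbp_summary(hist)
  i <- 1:6
  mu <- sum(i * h6)
  m2 <- sum((i - mu)^2 * h6)
  expect_equal(unname(s["mean"]), mu)
  expect_equal(unname(s["entropy"]),
               -sum(h6[h6 > 0] * log2(h6[h6 > 0])))
  expect_equal(unname(s["skewness"]), sum((i - mu)^3 * h6) / m2^1.5)
  expect_equal(unname(s["range"]), 4)
  expect_equal(unname(s["maxVal"]), 0.5)
  expect_equal(unname(s["argmax"]), 1)

  # unit mass at bin 5
  h1 <- numeric(12); h1[5] <- 1
  hist1 <- structure(list(h = h1, config = lbp_configs(1L)[[1]],
                          sample_count = 4L, degenerate = FALSE),
                     class = "lbp_histogram")
  s1 <- lbp_summary(hist1)
  expect_equal(unname(s1[c("mean", "std", "energy")]), c(5, 0, 1))
})

test_that("degenerate histograms yield flagged zeros", {
  # 2-voxel ROI in a 3x3x3 volume: no circle of radius 2 fits anywhere
  vol <- array(rnorm(27), c(3, 3, 3))
  msk <- array(0, c(3, 3, 3)); msk[1, 1, 1:2] <- 1
  q <- quantize_roi(volume_roi(vol, msk), 4)
  cfg <- lbp_configs(radii = 2L)[[1]]
  h <- lbp_top_histogram(q, cfg)
  s <- lbp_summary(h)
  expect_true(all(s == 0))
  expect_true(isTRUE(attr(s, "degenerate")))
})

test_that("the family enumerates 10 configurations x 10 statistics", {
  cfgs <- lbp_configs()
  expect_length(cfgs, 10)
  expect_equal(sum(vapply(cfgs, function(c) c$mapping == "riu2", logical(1))), 1)
  q <- random_qroi(d = c(7, 7, 7), seed = 3, p_roi = 1)
  f <- lbptop_features(q)
  expect_length(f, 100)
  expect_false(anyDuplicated(names(f)) > 0)
  expect_true(all(c("lbp_range_LBP3_ri", "lbp_skewness_LBP3_u",
                    "lbp_mean_LBP3_u", "lbp_range_LBP3") %in% names(f)))
})
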