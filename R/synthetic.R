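#' Specification of a synthetic two-class cohort
#'
#' Defaults state the published cohort: 50 adaptive vs 41 non-adaptive
#' patients and the Total-column category proportions of the patient
#' characteristics table (male 0.76, stage IIIB 0.40, histology
#' adenocarcinoma/squamous/NOS/unavailable 0.43/0.47/0.07/0.03, age
#' ~ Normal(71, 9.6)). Vocabularies the study does not tabulate (smoking,
#' T, N, mutation status) get fixed plausible stage-III distributions,
#' documented in the methods vignette. Texture parameters control the
#' phantom contrast between the heterogeneous (adaptive) and homogeneous
#' (non-adaptive) tumour interiors.
#'
#' @param n_adaptive,n_nonadaptive Class sizes (>= 2).
#' @param age_mean,age_sd Age distribution in years.
#' @param p_male,p_stage_iiib Bernoulli proportions.
#' @param p_histology Named proportions over the four histology levels.
#' @param p_smoking,p_t,p_n,p_egfr,p_alk Category proportions.
#' @param volume_dim Phantom edge length in voxels.
#' @param blob_scale Gaussian smoothing scale (voxels) of the intensity
#'   blobs inside an adaptive tumour.
#' @param contrast Intensity separation (HU) of the two mixture components
#'   in an adaptive tumour.
#' @param texture_noise_sd Within-component intensity noise (HU).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_adaptive = 50L, n_nonadaptive = 41L,
                        age_mean = 71, age_sd = 9.6,
                        p_male = 0.76, p_stage_iiib = 0.40,
                        p_histology = c(adenocarcinoma = 0.43, squamous = 0.47,
                                        NOS = 0.07, unavailable = 0.03),
                        p_smoking = c(never = 0.15, former = 0.45,
                                      current = 0.35, unknown = 0.05),
                        p_t = c(`1` = 0.10, `2` = 0.25, `3` = 0.35, `4` = 0.30),
                        p_n = c(`0` = 0.10, `1` = 0.15, `2` = 0.50, `3` = 0.25),
                        p_egfr = c(mutated = 0.10, `wild-type` = 0.60,
                                   unknown = 0.30),
                        p_alk = c(rearranged = 0.05, negative = 0.60,
                                  unknown = 0.35),
                        volume_dim = 48L, blob_scale = 2.5, contrast = 40,
                        texture_noise_sd = 12) {
  if (n_adaptive < 2L || n_nonadaptive < 2L) abort("Class counts must be >= 2.")
  props <- list(p_male = p_male, p_stage_iiib = p_stage_iiib)
  for (p in c(props, as.list(p_histology), as.list(p_smoking), as.list(p_t),
              as.list(p_n), as.list(p_egfr), as.list(p_alk))) {
    if (!is.finite(p) || p < 0 || p > 1) abort("Proportions must lie in [0, 1].")
  }
  structure(
    list(n_adaptive = as.integer(n_adaptive),
         n_nonadaptive = as.integer(n_nonadaptive),
         age_mean = age_mean, age_sd = age_sd, p_male = p_male,
         p_stage_iiib = p_stage_iiib, p_histology = p_histology,
         p_smoking = p_smoking, p_t = p_t, p_n = p_n, p_egfr = p_egfr,
         p_alk = p_alk, volume_dim = as.integer(volume_dim),
         blob_scale = blob_scale, contrast = contrast,
         texture_noise_sd = texture_noise_sd),
    class = "cohort_spec"
  )
}

# Separable 3D Gaussian smoothing (kernel truncated at 3 sigma).
gauss_smooth3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(x)
  smooth_axis <- function(arr, axis) {
    out <- array(0, d)
    for (o in -r:r) {
      w <- k[o + r + 1L]
      src <- pmin(pmax(seq_len(d[axis]) + o, 1L), d[axis])  # replicate edges
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[axis]] <- src
      out <- out + w * arr[idx[[1]], idx[[2]], idx[[3]]]
    }
    out
  }
  for (axis in 1:3) x <- smooth_axis(x, axis)
  x
}

#' Generate a synthetic CT phantom with known class
#'
#' Stands in for a planning CT: a cube of Gaussian lung-density background
#' noise containing an ellipsoidal tumour ROI with random semi-axes of
#' 8-14 voxels. A `non-adaptive` tumour interior is a single smoothed
#' intensity component (homogeneous texture); an `adaptive` tumour is a
#' two-component mixture arranged in smoothed random blobs (heterogeneous
#' texture), so co-occurrence and LBP features carry class signal. A
#' semantic record is drawn from the cohort's categorical proportions.
#'
#' @param class_label `"adaptive"` or `"non-adaptive"`.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the phantom is byte-identical for a given
#'   seed.
#' @return A list with `roi` ([volume_roi()]), `semantic`
#'   ([semantic_record()]) and `class`.
#' @export
generate_phantom <- function(class_label = c("adaptive", "non-adaptive"),
                             spec = cohort_spec(), seed = 1L) {
  class_label <- match.arg(class_label)
  d <- spec$volume_dim
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    vol <- array(rnorm(d^3, mean = -750, sd = 40), c(d, d, d))

    ctr <- d / 2 + runif(3, -2, 2)
    ax <- runif(3, 8, 14)
    gr <- seq_len(d)
    dist2 <- outer(outer((gr - ctr[1])^2 / ax[1]^2,
                         (gr - ctr[2])^2 / ax[2]^2, "+"),
                   (gr - ctr[3])^2 / ax[3]^2, "+")
    mask <- array(as.integer(dist2 <= 1), c(d, d, d))

    base <- gauss_smooth3d(array(rnorm(d^3, 0, spec$texture_noise_sd),
                                 c(d, d, d)), 1)
    tumour <- 30 + base
    if (class_label == "adaptive") {
      blob <- gauss_smooth3d(array(rnorm(d^3), c(d, d, d)), spec$blob_scale)
      comp <- blob > stats::median(blob[mask == 1L])
      tumour <- tumour + ifelse(comp, spec$contrast / 2, -spec$contrast / 2)
    }
    vol[mask == 1L] <- tumour[mask == 1L]

    sem <- random_semantic_record(spec)
    roi <- volume_roi(vol, mask,
                      patient_id = sprintf("phantom_%s_%d", class_label, seed))
  })
  list(roi = roi, semantic = sem, class = class_label)
}

# Draw one semantic record from the cohort's categorical proportions
# (consumes the current RNG stream).
random_semantic_record <- function(spec) {
  pick <- function(p) sample(names(p), 1L, prob = p)
  semantic_record(
    age = max(30, round(rnorm(1, spec$age_mean, spec$age_sd))),
    sex = if (runif(1) < spec$p_male) "M" else "F",
    smoking = pick(spec$p_smoking),
    T = as.integer(pick(spec$p_t)),
    N = as.integer(pick(spec$p_n)),
    stage = if (runif(1) < spec$p_stage_iiib) "IIIB" else "IIIA",
    histology = pick(spec$p_histology),
    egfr = pick(spec$p_egfr),
    alk = pick(spec$p_alk)
  )
}

#' Generate a synthetic phantom cohort
#'
#' Draws `n_adaptive` + `n_nonadaptive` phantoms (seeds `seed + 1, ...`)
#' and returns them with labels, ready for [extract_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Master seed.
#' @return A list with `rois`, `semantics`, `labels`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  labels <- rep(c("adaptive", "non-adaptive"),
                c(spec$n_adaptive, spec$n_nonadaptive))
  phantoms <- lapply(seq_along(labels), function(i) {
    generate_phantom(labels[i], spec, seed = seed + i)
  })
  list(rois = lapply(phantoms, `[[`, "roi"),
       semantics = lapply(phantoms, `[[`, "semantic"),
       labels = labels)
}

#' Generate a synthetic feature table with planted signal
#'
#' Tabular ground truth for testing selection and evaluation without image
#' extraction: `k_informative` columns are Normal(d, 1) in the positive
#' class and Normal(0, 1) otherwise; the remaining columns are Normal(0,
#' 1) in both classes. Column names are drawn from the real 251-feature
#' registry so tables look like genuine extractions; which of them carry
#' signal is chosen at random (seeded) and returned.
#'
#' @param n Number of rows (>= 4).
#' @param p Number of feature columns (<= 251).
#' @param k_informative Number of signal-carrying columns (<= p).
#' @param d Effect size: class-mean separation in SD units.
#' @param class_balance Positive-class proportion (default 50/91, the
#'   published cohort balance).
#' @param seed Integer seed; the table is identical for a given seed.
#' @return A list with `table` (feature table tibble) and `informative`
#'   (character vector of signal column names).
#' @export
generate_feature_table <- function(n = 91L, p = 50L, k_informative = 5L,
                                   d = 1.5, class_balance = 50 / 91,
                                   seed = 1L) {
  if (n < 4L) abort("`n` must be at least 4.")
  if (k_informative > p) abort("`k_informative` must not exceed `p`.")
  if (p > 251L) abort("`p` must not exceed the registry size (251).")
  reg <- feature_registry()$name
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    cols <- sort(sample.int(251L, p))
    nm <- reg[cols]
    info <- sort(sample.int(p, k_informative))
    n1 <- max(2L, min(n - 2L, round(n * class_balance)))
    y <- rep(c(1L, 0L), c(n1, n - n1))
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, nm))
    for (j in info) X[y == 1L, j] <- X[y == 1L, j] + d
  })
  tab <- feature_table(X, ifelse(y == 1L, "adaptive", "non-adaptive"))
  list(table = tab, informative = nm[info])
}
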