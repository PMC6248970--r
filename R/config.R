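#' Pipeline run configuration
#'
#' Collects every tunable of the workflow in one validated object. Defaults
#' reproduce the published protocol where stated (selection threshold 10%,
#' split-candidate count m < p) and standard practice where the protocol is
#' silent (32 gray levels, LBP radii 1-3, 500-tree final forest, assumed
#' prevalence 0.40 from the reported 30-40% plan-adaptation rate).
#'
#' @param G Gray-level count for texture quantization (>= 2).
#' @param n_bins Bin count of the first-order intensity histogram.
#' @param lbp_radii LBP sampling radii, subset of 1:3.
#' @param tau Selection-frequency threshold in (0, 1]; a feature enters the
#'   signature if chosen in at least `tau` of the leave-one-out folds.
#' @param n_trees Tree count of the final Random Forest.
#' @param wrapper_trees Tree count of the (cheaper) wrapper-internal forest.
#' @param m Split-candidate count; `NULL` means `floor(sqrt(p))` at fit
#'   time, always capped below the feature count p.
#' @param B Bootstrap replicate count of the .632+ error estimate (>= 2).
#' @param prevalence Assumed positive-class prevalence for adjusted
#'   PPV/NPV, in (0, 1).
#' @param seed Integer master seed; all fold splits and forest randomness
#'   derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(G = 32L, n_bins = 64L, lbp_radii = c(1L, 2L, 3L),
                       tau = 0.10, n_trees = 500L, wrapper_trees = 100L,
                       m = NULL, B = 200L, prevalence = 0.40, seed = 1L) {
  if (G < 2) abort("`G` must be at least 2.")
  if (n_bins < 1) abort("`n_bins` must be positive.")
  if (!all(lbp_radii %in% 1:3) || length(lbp_radii) == 0) {
    abort("`lbp_radii` must be a non-empty subset of 1:3.")
  }
  if (!(tau > 0 && tau <= 1)) abort("`tau` must lie in (0, 1].")
  if (B < 2) abort("`B` must be at least 2.")
  if (!(prevalence > 0 && prevalence < 1)) {
    abort("`prevalence` must lie in (0, 1).")
  }
  if (n_trees < 1 || wrapper_trees < 1) abort("tree counts must be positive.")
  structure(
    list(G = as.integer(G), n_bins = as.integer(n_bins),
         lbp_radii = as.integer(lbp_radii), tau = tau,
         n_trees = as.integer(n_trees),
         wrapper_trees = as.integer(wrapper_trees),
         m = if (is.null(m)) NULL else as.integer(m),
         B = as.integer(B), prevalence = prevalence,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Random-Forest hyperparameters
#'
#' @param n_trees Number of trees.
#' @param m Split-candidate count (`NULL`: `floor(sqrt(p))`); must satisfy
#'   m < p when the feature count p exceeds 1.
#' @param seed Integer seed for bootstrap samples and feature draws.
#' @return A list of class `rf_params`.
#' @export
rf_params <- function(n_trees = 500L, m = NULL, seed = 1L) {
  if (n_trees < 1) abort("`n_trees` must be positive.")
  structure(list(n_trees = as.integer(n_trees),
                 m = if (is.null(m)) NULL else as.integer(m),
                 seed = as.integer(seed)),
            class = "rf_params")
}

# Resolve m for p features: floor(sqrt(p)) by default, always < p for p > 1.
resolve_mtry <- function(m, p) {
  if (p < 1) abort("No features to split on.")
  if (is.null(m)) m <- max(1L, floor(sqrt(p)))
  if (p > 1L && m >= p) {
    abort(sprintf("Split-candidate count m (%d) must be smaller than the feature count p (%d).",
                  m, p))
  }
  as.integer(max(1L, min(m, p)))
}
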