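#' Extract the full 251-feature vector of one patient
#'
#' Runs the complete radiomic extraction on a volume + ROI pair: 12
#' first-order statistics on the raw in-ROI intensities, then quantization
#' to `config$G` gray levels followed by 130 co-occurrence and 100 LBP-TOP
#' texture features, and finally the 9 encoded semantic features. The
#' result is always laid out in registry order ([feature_registry()]).
#'
#' @param roi A [volume_roi()].
#' @param semantic A [semantic_record()], or `NULL` to fill the semantic
#'   block with `NA` (permitted: semantic columns are the only ones that
#'   may be missing).
#' @param config A [run_config()].
#' @return Named numeric vector of length 251.
#' @export
extract_features <- function(roi, semantic = NULL, config = run_config()) {
  stopifnot(inherits(roi, "volume_roi"))
  fo <- firstorder_features(roi_intensities(roi), config$n_bins)
  q <- quantize_roi(roi, config$G)
  gl <- glcm_features(q)
  lb <- lbptop_features(q, config$lbp_radii)
  sem <- if (is.null(semantic)) {
    stats::setNames(rep(NA_real_, 9L), paste0("sem_", semantic_field_names()))
  } else {
    encode_semantic(semantic)
  }
  out <- c(fo, gl, lb, sem)
  reg <- feature_registry()$name
  if (!identical(names(out), reg)) {
    # only possible with non-default lbp radii; keep whatever was computed
    if (setequal(names(out), reg)) out <- out[reg]
  }
  out
}

#' Extract a feature table for a cohort
#'
#' One row per patient, 251 named feature columns plus `patient_id` and
#' `class`, deterministic given its inputs. Any failed extraction aborts
#' naming the patient.
#'
#' @param rois List of [volume_roi()] objects (or pairs of file paths,
#'   `list(volume =, mask =)`, read via [read_volume_roi()]).
#' @param semantics List of [semantic_record()]s aligned with `rois`, or
#'   `NULL`.
#' @param labels Character vector of class labels (`adaptive` /
#'   `non-adaptive`), aligned with `rois`.
#' @param config A [run_config()].
#' @return A validated feature table tibble.
#' @export
extract_cohort <- function(rois, labels, semantics = NULL,
                           config = run_config()) {
  if (length(rois) < 1L) abort("Need at least one volume + ROI pair.")
  if (length(labels) != length(rois)) {
    abort("`labels` must align with `rois`.")
  }
  if (!is.null(semantics) && length(semantics) != length(rois)) {
    abort("`semantics` must align with `rois`.")
  }
  rows <- vector("list", length(rois))
  ids <- character(length(rois))
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    if (!inherits(roi, "volume_roi")) {
      roi <- read_volume_roi(roi$volume, roi$mask)
    }
    ids[i] <- roi$patient_id
    rows[[i]] <- tryCatch(
      extract_features(roi, semantics[[i]], config),
      error = function(e) {
        abort(sprintf("Feature extraction failed for patient '%s': %s",
                      roi$patient_id, conditionMessage(e)))
      }
    )
  }
  feats <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  feature_table(feats, labels, ids)
}
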