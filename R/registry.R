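#' The fixed inventory of all 251 features
#'
#' The pipeline computes a fixed, ordered set of 251 named features per
#' patient: 12 first-order histogram statistics, 130 gray-level
#' co-occurrence (GLCM) features (10 statistics for each of the 13
#' canonical displacement directions), 100 LBP-TOP features (10
#' distribution statistics for each of 10 pattern configurations) and 9
#' semantic (clinician-scored) features. The registry guarantees a stable
#' vector layout: every feature table produced by [extract_features()]
#' carries its columns in this order.
#'
#' Feature names follow the conventions of the original signature report:
#' `stat_<name>` for first-order statistics (e.g. `stat_numMaxRel`),
#' `glcm_<stat>_<dx>,<dy>,<dz>` for co-occurrence statistics (e.g.
#' `glcm_absolute_-1,1,-1`), `lbp_<stat>_LBP<R>[_<mapping>]` for LBP-TOP
#' (e.g. `lbp_range_LBP3_ri`), and `sem_<field>` for semantic features.
#'
#' @return A tibble with columns `name` and `family`
#'   (`firstorder`/`glcm`/`lbptop`/`semantic`), 251 rows, in canonical
#'   order.
#' @examples
#' reg <- feature_registry()
#' table(reg$family)
#' @export
feature_registry <- function() {
  fo <- paste0("stat_", firstorder_stat_names())

  dirs <- glcm_directions()
  dir_tags <- vapply(dirs, function(d) paste(d, collapse = ","), character(1))
  gl <- as.vector(t(outer(glcm_stat_names(), dir_tags,
                          function(s, d) paste0("glcm_", s, "_", d))))

  lb <- unlist(lapply(lbp_configs(), function(cfg) {
    paste0("lbp_", lbp_stat_names(), "_", lbp_config_tag(cfg))
  }), use.names = FALSE)

  sem <- paste0("sem_", semantic_field_names())

  tibble(
    name = c(fo, gl, lb, sem),
    family = rep(c("firstorder", "glcm", "lbptop", "semantic"),
                 c(length(fo), length(gl), length(lb), length(sem)))
  )
}

firstorder_stat_names <- function() {
  c("mean", "std", "skewness", "kurtosis", "width", "energy", "entropy",
    "maxVal", "maxPos", "energyAroundMax", "numMaxRel", "energyRelMax")
}

glcm_stat_names <- function() {
  c("energy", "entropy", "inertia", "absolute", "idm", "correlation",
    "sumAverage", "variance", "clusterShade", "clusterProminence")
}

lbp_stat_names <- function() {
  c("mean", "std", "skewness", "kurtosis", "range", "energy", "entropy",
    "maxVal", "argmax", "numMaxRel")
}

semantic_field_names <- function() {
  c("age", "sex", "smoking", "T", "N", "stage", "histology", "egfr", "alk")
}

#' Feature-family membership by name
#'
#' Maps registry-style feature names to their family by prefix; used by the
#' ablation options of [run_signature_pipeline()].
#'
#' @param names Character vector of feature names.
#' @return Character vector: `"firstorder"`, `"glcm"`, `"lbptop"`,
#'   `"semantic"` or `"other"`.
#' @export
feature_family <- function(names) {
  out <- rep("other", length(names))
  out[startsWith(names, "stat_")] <- "firstorder"
  out[startsWith(names, "glcm_")] <- "glcm"
  out[startsWith(names, "lbp_")] <- "lbptop"
  out[startsWith(names, "sem_")] <- "semantic"
  out
}
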