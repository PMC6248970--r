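#' A clinician-scored semantic record
#'
#' The nine semantic features scored by radiation oncologists on the
#' planning CT: personal data (age, sex, smoking attitude), staging scores
#' (T, N, tumour stage) and tissue characterization (histology, EGFR and
#' ALK status). `unknown` is a value, not an absence: all nine fields must
#' be present.
#'
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param smoking `"never"`, `"former"`, `"current"` or `"unknown"`.
#' @param T,N Tumour/node staging scores: T in 1..4, N in 0..3.
#' @param stage `"IIIA"` or `"IIIB"`.
#' @param histology `"adenocarcinoma"`, `"squamous"`, `"NOS"` or
#'   `"unavailable"`.
#' @param egfr `"mutated"`, `"wild-type"` or `"unknown"`.
#' @param alk `"rearranged"`, `"negative"` or `"unknown"`.
#' @return A list of class `semantic_record`.
#' @examples
#' rec <- semantic_record(71, "M", "former", 4, 2, "IIIB",
#'                        "squamous", "wild-type", "negative")
#' encode_semantic(rec)
#' @export
semantic_record <- function(age, sex, smoking, T, N, stage, histology,
                            egfr, alk) {
  rec <- list(age = age, sex = sex, smoking = smoking, T = T, N = N,
              stage = stage, histology = histology, egfr = egfr, alk = alk)
  check_level <- function(field, vocab) {
    v <- rec[[field]]
    if (length(v) != 1L || is.na(v) || !v %in% vocab) {
      abort(sprintf("Invalid value '%s' for semantic field `%s` (allowed: %s).",
                    as.character(v), field, paste(vocab, collapse = ", ")))
    }
  }
  if (length(age) != 1L || !is.finite(age) || age < 0) {
    abort(sprintf("Invalid value '%s' for semantic field `age`.", age))
  }
  check_level("sex", c("M", "F"))
  check_level("smoking", c("never", "former", "current", "unknown"))
  check_level("T", as.character(1:4))
  check_level("N", as.character(0:3))
  check_level("stage", c("IIIA", "IIIB"))
  check_level("histology", c("adenocarcinoma", "squamous", "NOS", "unavailable"))
  check_level("egfr", c("mutated", "wild-type", "unknown"))
  check_level("alk", c("rearranged", "negative", "unknown"))
  rec$age <- as.numeric(age)
  rec$T <- as.integer(as.character(T))
  rec$N <- as.integer(as.character(N))
  structure(rec, class = "semantic_record")
}

#' Encode a semantic record as nine numeric features
#'
#' Integer coding (not one-hot) because the downstream learner is
#' tree-based and the published signature treats each semantic item as one
#' feature. Ordinal fields keep their order; `unknown`-type categories get
#' the sentinel -1 where they are not a natural ordinal level.
#'
#' Codes: age as-is; sex M=0, F=1; smoking never=0, former=1, current=2,
#' unknown=-1; T and N as given; stage IIIA=0, IIIB=1; histology
#' adenocarcinoma=0, squamous=1, NOS=2, unavailable=3; EGFR mutated=1,
#' wild-type=0, unknown=-1; ALK rearranged=1, negative=0, unknown=-1.
#'
#' @param rec A [semantic_record()] (or a list/1-row data frame with the
#'   same nine fields, which is validated first).
#' @return Named numeric vector `sem_age` ... `sem_alk` in registry order.
#' @export
encode_semantic <- function(rec) {
  if (!inherits(rec, "semantic_record")) {
    rec <- do.call(semantic_record,
                   lapply(semantic_field_names(), function(f) {
                     v <- rec[[f]]
                     if (is.null(v)) abort(sprintf("Semantic field `%s` is missing.", f))
                     v
                   }) |> stats::setNames(semantic_field_names()))
  }
  code <- function(v, vocab, codes) codes[match(v, vocab)]
  out <- c(
    age = rec$age,
    sex = code(rec$sex, c("M", "F"), c(0, 1)),
    smoking = code(rec$smoking, c("never", "former", "current", "unknown"),
                   c(0, 1, 2, -1)),
    T = as.numeric(rec$T),
    N = as.numeric(rec$N),
    stage = code(rec$stage, c("IIIA", "IIIB"), c(0, 1)),
    histology = code(rec$histology,
                     c("adenocarcinoma", "squamous", "NOS", "unavailable"),
                     c(0, 1, 2, 3)),
    egfr = code(rec$egfr, c("mutated", "wild-type", "unknown"), c(1, 0, -1)),
    alk = code(rec$alk, c("rearranged", "negative", "unknown"), c(1, 0, -1))
  )
  names(out) <- paste0("sem_", semantic_field_names())
  out
}
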