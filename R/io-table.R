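#' Assemble a feature table
#'
#' A feature table is the tabular interface between extraction and
#' modelling: one row per patient, a `patient_id` column, a binary `class`
#' label (`adaptive` / `non-adaptive`), and one numeric column per feature
#' in registry order. Missing values are permitted only in semantic
#' (`sem_`-prefixed) columns.
#'
#' @param features Data frame or matrix of numeric feature columns.
#' @param labels Character/factor vector of class labels, two distinct
#'   values.
#' @param patient_ids Character vector of identifiers (default `pt001`...).
#' @return A tibble with columns `patient_id`, `class`, then the features.
#' @export
feature_table <- function(features, labels,
                          patient_ids = sprintf("pt%03d", seq_len(nrow(features)))) {
  features <- as_tibble(as.data.frame(features, check.names = FALSE))
  tab <- bind_cols(
    tibble(patient_id = as.character(patient_ids),
           class = as.character(labels)),
    features
  )
  validate_feature_table(tab)
}

#' Validate a feature table
#'
#' Checks the structural contract: `patient_id` and `class` columns, at
#' least one feature column, exactly two label values, all feature columns
#' numeric, and missing values confined to semantic columns.
#'
#' @param tab A data frame as returned by [feature_table()].
#' @return `tab` as a tibble, invisibly usable in pipes.
#' @export
validate_feature_table <- function(tab) {
  tab <- as_tibble(tab)
  if (!all(c("patient_id", "class") %in% names(tab))) {
    abort("A feature table needs `patient_id` and `class` columns.")
  }
  feats <- table_feature_names(tab)
  if (length(feats) == 0L) abort("A feature table needs at least one feature column.")
  labs <- unique(as.character(tab$class))
  if (length(labs) != 2L) {
    abort(sprintf("`class` must take exactly 2 values, found %d (%s).",
                  length(labs), paste(utils::head(labs, 5), collapse = ", ")))
  }
  for (f in feats) {
    col <- tab[[f]]
    if (!is.numeric(col)) {
      abort(sprintf("Feature column `%s` is not numeric.", f))
    }
    if (anyNA(col) && !startsWith(f, "sem_")) {
      abort(sprintf(
        "Missing values in radiomic column `%s` (only semantic columns may be missing).", f
      ))
    }
  }
  tab
}

#' Feature columns of a table
#'
#' @param tab A feature table.
#' @return Character vector of feature column names (everything except
#'   `patient_id` and `class`), in table order.
#' @export
table_feature_names <- function(tab) {
  setdiff(names(tab), c("patient_id", "class"))
}

# The class treated as "positive" throughout selection and evaluation.
positive_label <- function(tab, positive_class = NULL) {
  labs <- sort(unique(as.character(tab$class)))
  if (!is.null(positive_class)) {
    if (!positive_class %in% labs) {
      abort(sprintf("positive_class '%s' not among labels (%s).",
                    positive_class, paste(labs, collapse = ", ")))
    }
    return(positive_class)
  }
  if ("adaptive" %in% labs) "adaptive" else labs[1]
}

#' Read a feature table from ARFF or CSV
#'
#' The deposited datasets of this workflow circulate as Weka ARFF files
#' (`@relation` / `@attribute` / `@data`) with a two-valued nominal class
#' attribute; CSV mirrors the same layout with a header row and a label
#' column named `class`. Nominal non-class attributes are integer-coded
#' (0-based, in declaration order) and the coding is recorded in the
#' `"codings"` attribute of the result. A string/identifier attribute named
#' `patient_id` (or `id`) supplies row identifiers; otherwise `row_<i>` ids
#' are generated.
#'
#' @param path File to read.
#' @param dialect `"arff"` or `"csv"`; inferred from the extension by
#'   default.
#' @return A validated feature table tibble (see [feature_table()]).
#' @export
read_feature_table <- function(path, dialect = c("auto", "arff", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (dialect == "arff") read_arff_table(path) else read_csv_table(path)
}

#' Write a feature table to ARFF or CSV
#'
#' Inverse of [read_feature_table()]: `read(write(tab))` reproduces the
#' table (feature names byte-for-byte, values to at least 1e-9).
#'
#' @param tab A feature table.
#' @param path Output file.
#' @param dialect `"arff"` or `"csv"`; inferred from the extension by
#'   default.
#' @param relation ARFF `@relation` name.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tab, path, dialect = c("auto", "arff", "csv"),
                                relation = "radsig_features") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  tab <- validate_feature_table(tab)
  if (dialect == "arff") {
    write_arff_table(tab, path, relation)
  } else {
    readr::write_csv(tab, path)
  }
  invisible(path)
}

# ---- CSV ------------------------------------------------------------------

read_csv_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  if (!"class" %in% names(tab)) {
    abort(sprintf("CSV feature table needs a `class` label column: %s", path))
  }
  id_col <- intersect(c("patient_id", "id"), names(tab))[1]
  ids <- if (!is.na(id_col)) as.character(tab[[id_col]]) else {
    sprintf("row_%d", seq_len(nrow(tab)))
  }
  feats <- tab[setdiff(names(tab), c("class", "patient_id", "id"))]
  codings <- list()
  for (f in names(feats)) {
    if (!is.numeric(feats[[f]])) {
      lev <- unique(feats[[f]][!is.na(feats[[f]])])
      codings[[f]] <- lev
      feats[[f]] <- as.numeric(match(feats[[f]], lev) - 1L)
    }
  }
  out <- feature_table(feats, tab$class, ids)
  attr(out, "codings") <- codings
  out
}

# ---- ARFF (Weka dialect) --------------------------------------------------
# No ARFF reader ships with this R stack (RWeka/farff/foreign are absent),
# so the Weka dialect is parsed directly: @relation, @attribute
# (numeric/real/integer, nominal {a,b,...}, string), '%' comments, '?'
# missing, optional single-quoted names containing spaces or commas.

arff_quote <- function(x) {
  needs <- grepl("[ ,{}'\"%\t]", x) | x == ""
  x[needs] <- paste0("'", gsub("'", "\\\\'", x[needs]), "'")
  x
}

# Split a @data line or nominal spec on commas, honouring single quotes.
arff_split <- function(line) {
  out <- character(0)
  buf <- character(0)
  in_q <- FALSE
  chars <- strsplit(line, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_q) {
      if (ch == "\\" && i < length(chars) && chars[i + 1] == "'") {
        buf <- c(buf, "'"); i <- i + 1L
      } else if (ch == "'") {
        in_q <- FALSE
      } else buf <- c(buf, ch)
    } else if (ch == "'") {
      in_q <- TRUE
    } else if (ch == ",") {
      out <- c(out, paste(buf, collapse = "")); buf <- character(0)
    } else buf <- c(buf, ch)
    i <- i + 1L
  }
  trimws(c(out, paste(buf, collapse = "")))
}

read_arff_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*%", lines) & nzchar(trimws(lines))]
  is_attr <- grepl("^\\s*@attribute", lines, ignore.case = TRUE)
  data_at <- which(grepl("^\\s*@data", lines, ignore.case = TRUE))[1]
  if (is.na(data_at)) abort(sprintf("No @data section in ARFF file: %s", path))

  attr_lines <- lines[seq_len(data_at - 1)][is_attr[seq_len(data_at - 1)]]
  specs <- lapply(attr_lines, function(l) {
    body <- trimws(sub("^\\s*@attribute\\s+", "", l, ignore.case = TRUE))
    if (startsWith(body, "'")) {
      m <- regmatches(body, regexpr("^'(\\\\'|[^'])*'", body))
      name <- gsub("\\\\'", "'", substr(m, 2, nchar(m) - 1))
      rest <- trimws(substr(body, nchar(m) + 1, nchar(body)))
    } else {
      sp <- regexpr("\\s", body)
      if (sp < 0) abort(sprintf("Malformed @attribute line: %s", l))
      name <- substr(body, 1, sp - 1)
      rest <- trimws(substr(body, sp + 1, nchar(body)))
    }
    if (startsWith(rest, "{")) {
      levels <- arff_split(gsub("^\\{|\\}$", "", trimws(rest)))
      list(name = name, type = "nominal", levels = levels)
    } else {
      ty <- tolower(rest)
      ty <- if (ty %in% c("numeric", "real", "integer")) "numeric"
            else if (ty == "string") "string"
            else abort(sprintf("Unsupported ARFF attribute type '%s' (%s)", rest, name))
      list(name = name, type = ty, levels = NULL)
    }
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")

  data_lines <- lines[(data_at + 1):length(lines)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  cells <- lapply(data_lines, arff_split)
  bad <- which(lengths(cells) != length(specs))
  if (length(bad)) {
    abort(sprintf("ARFF row %d has %d values, expected %d attributes.",
                  bad[1], lengths(cells)[bad[1]], length(specs)))
  }
  mat <- do.call(rbind, cells)

  # class attribute: prefer one literally named "class", else the last
  # two-valued nominal attribute
  nm_lower <- tolower(names(specs))
  cls_idx <- which(nm_lower == "class")
  if (length(cls_idx) == 0L) {
    nominal2 <- which(vapply(specs, function(s) s$type == "nominal", logical(1)))
    cls_idx <- nominal2[vapply(specs[nominal2],
                               function(s) length(s$levels) == 2L, logical(1))]
    if (length(cls_idx) == 0L) {
      abort(sprintf("No two-valued nominal class attribute in %s", path))
    }
    cls_idx <- cls_idx[length(cls_idx)]
  } else cls_idx <- cls_idx[1]
  cls_spec <- specs[[cls_idx]]
  if (cls_spec$type != "nominal" || length(cls_spec$levels) != 2L) {
    abort(sprintf("Class attribute '%s' must be nominal with 2 values, found %d.",
                  cls_spec$name, length(cls_spec$levels)))
  }
  cls_raw <- mat[, cls_idx]
  if (any(!cls_raw %in% c(cls_spec$levels, "?"))) {
    bad_v <- setdiff(unique(cls_raw), c(cls_spec$levels, "?"))
    abort(sprintf("Undeclared class value '%s' in %s", bad_v[1], path))
  }
  if (any(cls_raw == "?")) abort(sprintf("Missing class labels in %s", path))

  id_idx <- which(nm_lower %in% c("patient_id", "id") &
                  vapply(specs, function(s) s$type == "string", logical(1)))
  ids <- if (length(id_idx)) mat[, id_idx[1]] else sprintf("row_%d", seq_len(nrow(mat)))

  feat_idx <- setdiff(seq_along(specs), c(cls_idx, id_idx[1]))
  feat_idx <- feat_idx[!is.na(feat_idx)]
  codings <- list()
  feats <- lapply(feat_idx, function(j) {
    s <- specs[[j]]
    col <- mat[, j]
    col[col == "?"] <- NA
    if (s$type == "nominal") {
      bad_v <- setdiff(col[!is.na(col)], s$levels)
      if (length(bad_v)) {
        abort(sprintf("Undeclared nominal value '%s' for attribute '%s'.",
                      bad_v[1], s$name))
      }
      codings[[s$name]] <<- s$levels
      as.numeric(match(col, s$levels) - 1L)
    } else if (s$type == "string") {
      codings[[s$name]] <<- sort(unique(col[!is.na(col)]))
      as.numeric(match(col, codings[[s$name]]) - 1L)
    } else {
      suppressWarnings(v <- as.numeric(col))
      if (any(is.na(v) & !is.na(col))) {
        abort(sprintf("Non-numeric value '%s' in numeric attribute '%s'.",
                      col[which(is.na(v) & !is.na(col))[1]], s$name))
      }
      v
    }
  })
  names(feats) <- names(specs)[feat_idx]
  out <- feature_table(as.data.frame(feats, check.names = FALSE,
                                     optional = TRUE),
                       cls_raw, ids)
  attr(out, "codings") <- codings
  out
}

write_arff_table <- function(tab, path, relation) {
  feats <- table_feature_names(tab)
  labs <- sort(unique(as.character(tab$class)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@relation %s", arff_quote(relation)), con)
  writeLines("", con)
  writeLines("@attribute patient_id string", con)
  writeLines(sprintf("@attribute %s numeric", arff_quote(feats)), con)
  writeLines(sprintf("@attribute class {%s}",
                     paste(arff_quote(labs), collapse = ",")), con)
  writeLines("", con)
  writeLines("@data", con)
  vals <- vapply(feats, function(f) {
    v <- format(tab[[f]], digits = 17, trim = TRUE, scientific = FALSE)
    v[is.na(tab[[f]])] <- "?"
    v
  }, character(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab))
  rows <- apply(cbind(arff_quote(tab$patient_id), vals,
                      arff_quote(as.character(tab$class))),
                1, paste, collapse = ",")
  writeLines(rows, con)
  invisible(path)
}
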