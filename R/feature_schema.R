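#' Tongue-feature vocabulary and numeric code tables
#'
#' The classifier works on eight tongue features recorded by TCM
#' practitioners: tongue body (shape), tongue colour, four surface marks
#' (red spots, black spots, fissures, petechiae — a record may show any
#' subset), teeth markings, fur (coating) colour, fur thickness and saliva.
#' `tongue_schema()` returns the category vocabulary together with the
#' numeric code table used by [encode_records()].
#'
#' Two encoding schemes are provided. Both map every category to a code in
#' \[0, 1\] and produce a length-8 vector per record, in the fixed order
#' `tongue_color, tongue_body, fur_color, fur_thickness, spot_score,
#' saliva, fissures, teeth_markings`:
#' * `"ordinal"` — categories uniformly spaced in \[0, 1\] in the order the
#'   vocabulary lists them.
#' * `"severity"` — the same uniform spacing, but categories re-ordered from
#'   clinically unremarkable to most strongly diabetes-associated (e.g. fur
#'   thickness thin < no fur < thick).
#'
#' The three countable surface marks (red spots, black spots, petechiae)
#' enter as a single spot score, `count / 3`; fissures and teeth markings
#' are 0/1 flags.
#'
#' @param scheme `"ordinal"` (default) or `"severity"`.
#' @return A list with elements `levels` (named list of category vectors),
#'   `codes` (named list of named numeric code vectors), `surface_flags`
#'   (names of the boolean surface-mark columns), `vector_names` (the eight
#'   encoded coordinates, in order) and `scheme`.
#' @examples
#' tongue_schema()$codes$fur_thickness
#' @export
tongue_schema <- function(scheme = c("ordinal", "severity")) {
  scheme <- match.arg(scheme)
  levels <- list(
    tongue_body   = c("medium", "enlarged", "small"),
    tongue_color  = c("mild_red", "red", "pale", "bluish"),
    fur_color     = c("white", "black", "yellow", "none"),
    fur_thickness = c("thin", "thick", "no_fur"),
    saliva        = c("normal", "dry", "wet")
  )
  severity_order <- list(
    tongue_body   = c("medium", "small", "enlarged"),
    tongue_color  = c("mild_red", "pale", "red", "bluish"),
    fur_color     = c("white", "none", "black", "yellow"),
    fur_thickness = c("thin", "no_fur", "thick"),
    saliva        = c("normal", "wet", "dry")
  )
  ordered <- if (scheme == "ordinal") levels else severity_order
  codes <- lapply(ordered, function(ord) {
    stats::setNames((seq_along(ord) - 1) / (length(ord) - 1), ord)
  })
  list(
    levels = levels,
    codes = codes,
    surface_flags = c("red_spots", "black_spots", "fissures", "petechiae"),
    flag_features = c("teeth_markings"),
    vector_names = c("tongue_color", "tongue_body", "fur_color", "fur_thickness",
                     "spot_score", "saliva", "fissures", "teeth_markings"),
    label_levels = c("non_DM", "DM"),
    scheme = scheme
  )
}

# canonical column order of a feature table
schema_columns <- function(with_label = TRUE) {
  cols <- c("tongue_body", "tongue_color", "red_spots", "black_spots",
            "fissures", "petechiae", "teeth_markings", "fur_color",
            "saliva", "fur_thickness")
  if (with_label) c(cols, "label") else cols
}

# validate a record data.frame against the vocabulary; row numbers are kept
# for error reporting
validate_records <- function(records, require_label = TRUE) {
  schema <- tongue_schema()
  if (!is.data.frame(records)) {
    tn_stop("schema_error", "records must be a data.frame, got %s", class(records)[1])
  }
  needed <- schema_columns(with_label = FALSE)
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    tn_stop("schema_error", "missing column(s): %s", paste(missing, collapse = ", "))
  }
  for (feat in names(schema$levels)) {
    vals <- as.character(records[[feat]])
    bad <- which(!vals %in% schema$levels[[feat]])
    if (length(bad)) {
      tn_stop("schema_error", "row %d: unknown %s value '%s'",
              bad[1], feat, vals[bad[1]])
    }
  }
  for (flag in c(schema$surface_flags, "teeth_markings")) {
    v <- records[[flag]]
    if (!is.logical(v)) {
      coerced <- parse_flag(v)
      if (anyNA(coerced)) {
        tn_stop("schema_error", "row %d: unparseable %s value '%s'",
                which(is.na(coerced))[1], flag, as.character(v[which(is.na(coerced))[1]]))
      }
      records[[flag]] <- coerced
    }
  }
  if ("label" %in% names(records)) {
    lab <- as.character(records$label)
    known <- lab %in% schema$label_levels | is.na(lab)
    if (!all(known)) {
      tn_stop("schema_error", "row %d: unknown label '%s'",
              which(!known)[1], lab[which(!known)[1]])
    }
    if (require_label && anyNA(lab)) {
      tn_stop("schema_error", "row %d: missing label", which(is.na(lab))[1])
    }
  } else if (require_label) {
    tn_stop("schema_error", "missing column(s): label")
  }
  records
}

parse_flag <- function(v) {
  if (is.logical(v)) return(v)
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[s %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Encode tongue records as numeric feature vectors
#'
#' Deterministically maps each record's categories to the length-8 numeric
#' vector the classifier consumes, using the code table of
#' [tongue_schema()]. All coordinates lie in \[0, 1\]. The mapping is
#' invertible for the single-valued features and the fissure/teeth flags;
#' the spot score only retains the *count* of red spots, black spots and
#' petechiae (see [decode_vector()]).
#'
#' @param records A data.frame of tongue records (see [read_feature_table()]
#'   for the column contract). The `label` column is optional: prediction-
#'   mode tables carry no label.
#' @param scheme Encoding scheme, `"ordinal"` or `"severity"`.
#' @return A numeric matrix with one row per record and columns
#'   `tongue_color, tongue_body, fur_color, fur_thickness, spot_score,
#'   saliva, fissures, teeth_markings`. If labels are present they are
#'   attached as a factor attribute `"label"` with levels `non_DM, DM`.
#' @seealso [decode_vector()], [tongue_schema()]
#' @export
encode_records <- function(records, scheme = c("ordinal", "severity")) {
  scheme <- match.arg(scheme)
  records <- validate_records(records, require_label = FALSE)
  schema <- tongue_schema(scheme)
  n <- nrow(records)
  spot_flags <- c("red_spots", "black_spots", "petechiae")
  spot_count <- rowSums(as.matrix(records[spot_flags])) # logical -> 0/1
  x <- cbind(
    tongue_color   = unname(schema$codes$tongue_color[as.character(records$tongue_color)]),
    tongue_body    = unname(schema$codes$tongue_body[as.character(records$tongue_body)]),
    fur_color      = unname(schema$codes$fur_color[as.character(records$fur_color)]),
    fur_thickness  = unname(schema$codes$fur_thickness[as.character(records$fur_thickness)]),
    spot_score     = spot_count / 3,
    saliva         = unname(schema$codes$saliva[as.character(records$saliva)]),
    fissures       = as.numeric(records$fissures),
    teeth_markings = as.numeric(records$teeth_markings)
  )
  if (!all(is.finite(x))) tn_stop("schema_error", "non-finite encoded value")
  if ("label" %in% names(records) && !all(is.na(records$label))) {
    attr(x, "label") <- factor(as.character(records$label),
                               levels = schema$label_levels)
  }
  x
}

#' Encode a single tongue record
#'
#' Convenience wrapper around [encode_records()] for one record given as a
#' named list or one-row data.frame.
#'
#' @inheritParams encode_records
#' @param record Named list or one-row data.frame with the schema columns.
#' @return A named numeric vector of length 8.
#' @export
encode_record <- function(record, scheme = c("ordinal", "severity")) {
  if (!is.data.frame(record)) record <- as.data.frame(record, stringsAsFactors = FALSE)
  m <- encode_records(record, scheme = match.arg(scheme))
  v <- m[1, ]
  attr(v, "label") <- if (!is.null(attr(m, "label"))) attr(m, "label")[1] else NULL
  v
}

#' Decode an encoded feature vector back to categories
#'
#' Inverts the documented encoding map: single-valued features and the two
#' 0/1 flags are recovered exactly; the spot score is returned as a count
#' (`n_spots`, 0–3) because the encoding does not retain which of the three
#' countable marks were present.
#'
#' @param x Numeric vector of length 8 as produced by [encode_record()].
#' @inheritParams encode_records
#' @return A named list of decoded categories plus `n_spots`.
#' @export
decode_vector <- function(x, scheme = c("ordinal", "severity")) {
  scheme <- match.arg(scheme)
  schema <- tongue_schema(scheme)
  if (length(x) != 8) tn_stop("schema_error", "expected a length-8 vector, got %d", length(x))
  nearest <- function(code, table) names(table)[which.min(abs(table - code))]
  list(
    tongue_color   = nearest(x[1], schema$codes$tongue_color),
    tongue_body    = nearest(x[2], schema$codes$tongue_body),
    fur_color      = nearest(x[3], schema$codes$fur_color),
    fur_thickness  = nearest(x[4], schema$codes$fur_thickness),
    n_spots        = as.integer(round(x[5] * 3)),
    saliva         = nearest(x[6], schema$codes$saliva),
    fissures       = x[7] >= 0.5,
    teeth_markings = x[8] >= 0.5
  )
}

#' Read a tongue feature table
#'
#' Reads a delimited text file (comma default, tab accepted) with a header
#' row of canonical column names: `tongue_body, tongue_color, red_spots,
#' black_spots, fissures, petechiae, teeth_markings, fur_color, saliva,
#' fur_thickness` and optionally `label` (and `phase`). Surface-mark and
#' teeth-marking columns accept TRUE/FALSE, 1/0 or yes/no. Category values
#' are validated against [tongue_schema()]; a bad cell raises a schema
#' error naming the row and value.
#'
#' @param path File path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @param require_label Require a complete label column (TRUE for
#'   training/evaluation tables; set FALSE for prediction-mode tables).
#' @return A data.frame of validated records, one row per participant.
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path, dialect = c("csv", "tsv"),
                               require_label = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) tn_stop("data_error", "no such file: %s", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  if (nrow(df) == 0) {
    missing <- setdiff(schema_columns(with_label = FALSE), names(df))
    if (length(missing)) {
      tn_stop("schema_error", "missing column(s): %s", paste(missing, collapse = ", "))
    }
    return(df)
  }
  for (flag in c("red_spots", "black_spots", "fissures", "petechiae", "teeth_markings")) {
    if (flag %in% names(df)) df[[flag]] <- parse_flag(df[[flag]])
  }
  if ("label" %in% names(df)) df$label[df$label == ""] <- NA
  validate_records(df, require_label = require_label)
}

#' Write a tongue feature table
#'
#' Writes records in the canonical delimited format read back by
#' [read_feature_table()]; a read/write round trip is byte-identical.
#'
#' @param records Validated record data.frame.
#' @param path Output file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  cols <- intersect(c(schema_columns(), "phase"), names(records))
  utils::write.table(records[cols], path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
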