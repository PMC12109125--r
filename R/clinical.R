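#' Declare a clinical covariate schema
#'
#' The schema drives ingestion and encoding of the clinical table: each
#' numeric field is min-max scaled to \[0, 1\] with statistics from the
#' training split only, and each categorical field is mapped to an ordinal
#' integer code 1..K in the declared category order, then scaled to
#' \[0, 1\] as `(code - 1) / (K - 1)`.
#'
#' @param numeric character vector of numeric column names (e.g. age, PSA).
#' @param categorical named list; each element is the ordered vector of
#'   admissible category values for that column (coded 1..K in this order).
#' @param label name of the binary outcome column (0/1).
#' @param id name of the patient identifier column.
#' @return A `bcr_clinical_schema` object.
#' @export
#' @examples
#' clinical_schema(
#'   numeric = c("age", "psa"),
#'   categorical = list(isup_grade = 1:5, clinical_stage = c("cT2x", "cT3x")))
clinical_schema <- function(numeric = c("age", "psa"),
                            categorical = list(
                              gleason_sum = c("<7", "=7", ">7"),
                              isup_grade = 1:5,
                              clinical_stage = c("cT2x", "cT3x"),
                              capra = c("<6", ">=6")),
                            label = "bcr_label", id = "patient_id") {
  stopifnot(is.character(numeric),
            is.list(categorical), length(names(categorical)) ==
              length(categorical))
  structure(list(numeric = numeric, categorical = categorical,
                 label = label, id = id),
            class = "bcr_clinical_schema")
}

schema_fields <- function(schema) c(schema$numeric, names(schema$categorical))

#' Read a clinical covariate table
#'
#' Reads a CSV with one row per patient, validates it against the schema
#' (no missing values, unique patient ids, known categories, label present
#' and binary) and maps categorical columns to their integer codes.
#'
#' @param path CSV file path (header row, comma separated).
#' @param schema a [clinical_schema()].
#' @return A tibble with the id column, numeric columns, coded categorical
#'   columns (integer), and the 0/1 label column.
#' @export
read_clinical_table <- function(path, schema = clinical_schema()) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  validate_clinical(df, schema)
}

#' @rdname read_clinical_table
#' @param df a data frame already in memory (columns may be character).
#' @export
validate_clinical <- function(df, schema = clinical_schema()) {
  need <- c(schema$id, schema_fields(schema), schema$label)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("clinical table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  df <- tibble::as_tibble(df)[need]
  for (col in need) {
    bad <- which(is.na(df[[col]]) | df[[col]] == "")
    if (length(bad))
      stop(sprintf("missing value in clinical column '%s' at row %d",
                   col, bad[1]))
  }
  ids <- as.character(df[[schema$id]])
  if (anyDuplicated(ids))
    stop("duplicate patient_id in clinical table: ",
         ids[duplicated(ids)][1])
  out <- tibble::tibble(.rows = length(ids))
  out[[schema$id]] <- ids
  for (col in schema$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in numeric clinical column '%s'", col))
    out[[col]] <- v
  }
  for (col in names(schema$categorical)) {
    cats <- as.character(schema$categorical[[col]])
    v <- as.character(df[[col]])
    code <- match(v, cats)
    if (anyNA(code))
      stop(sprintf(
        "unknown category '%s' in clinical column '%s' (expected one of: %s)",
        v[which(is.na(code))[1]], col, paste(cats, collapse = ", ")))
    out[[col]] <- as.integer(code)
  }
  y <- suppressWarnings(as.integer(df[[schema$label]]))
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("label column '", schema$label, "' must be 0/1 for every patient")
  out[[schema$label]] <- y
  out
}

#' Training-split scaling statistics for clinical encoding
#'
#' Computes per-field min/max over the given (training) rows only, so that
#' validation and test encodings never leak their own statistics.
#'
#' @param clinical validated clinical tibble ([read_clinical_table()]).
#' @param schema the matching [clinical_schema()].
#' @param train_ids patient ids of the training split; statistics are
#'   computed over these rows only (default: all rows).
#' @return A `bcr_clinical_stats` object (per-field min/max).
#' @export
clinical_stats <- function(clinical, schema = clinical_schema(),
                           train_ids = NULL) {
  if (!is.null(train_ids))
    clinical <- clinical[clinical[[schema$id]] %in% train_ids, , drop = FALSE]
  if (!nrow(clinical)) stop("no training rows to compute clinical statistics")
  stats <- lapply(schema$numeric, function(col)
    c(min = min(clinical[[col]]), max = max(clinical[[col]])))
  names(stats) <- schema$numeric
  structure(list(ranges = stats, schema = schema),
            class = "bcr_clinical_stats")
}

#' Encode clinical covariates to a \[0, 1\] vector
#'
#' Numeric fields are min-max scaled with *training* statistics and clipped
#' to \[0, 1\]; categorical codes 1..K become `(code - 1) / (K - 1)`. The
#' result is the flat clinical vector fed to the model.
#'
#' @param record one clinical row (tibble row or named list).
#' @param stats a [clinical_stats()] object carrying the schema.
#' @return Named numeric vector of length `D_cli`, all entries in \[0, 1\].
#' @export
encode_clinical <- function(record, stats) {
  schema <- stats$schema
  vals <- numeric(0)
  for (col in schema$numeric) {
    r <- stats$ranges[[col]]
    if (r["max"] - r["min"] <= 0)
      stop("degenerate clinical field '", col,
           "': training min equals max")
    v <- (as.numeric(record[[col]]) - r["min"]) / (r["max"] - r["min"])
    vals[col] <- min(1, max(0, v))
  }
  for (col in names(schema$categorical)) {
    k <- length(schema$categorical[[col]])
    code <- as.numeric(record[[col]])
    if (is.na(code) || code < 1 || code > k)
      stop("clinical code out of range for '", col, "'")
    vals[col] <- if (k > 1) (code - 1) / (k - 1) else 0
  }
  vals
}

#' @rdname encode_clinical
#' @param clinical a full validated clinical tibble.
#' @return `encode_clinical_table()`: a matrix, one row per patient
#'   (rownames = patient id).
#' @export
encode_clinical_table <- function(clinical, stats) {
  schema <- stats$schema
  m <- t(vapply(seq_len(nrow(clinical)),
                function(i) encode_clinical(clinical[i, ], stats),
                numeric(length(schema_fields(schema)))))
  rownames(m) <- clinical[[schema$id]]
  colnames(m) <- schema_fields(schema)
  m
}
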