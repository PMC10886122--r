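#' Construct a validated cohort
#'
#' A cohort bundles a subject-level table with its [cohort_schema()] and,
#' for synthetic cohorts, the generator ground truth. Validation enforces the
#' schema contract: every schema column present, unique subject identifiers,
#' ages within the declared range, and numeric IDP columns. Columns are
#' reordered to canonical schema order so that files written from a cohort
#' are deterministic.
#'
#' @param data a data.frame with one row per subject.
#' @param schema a [cohort_schema()].
#' @param truth optional `ground_truth` object (see [generate_cohort()]).
#' @return an object of class `cohort` with elements `schema`, `data`, `truth`.
#' @export
new_cohort <- function(data, schema, truth = NULL) {
  cols <- schema_columns(schema)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stopf("schema_error", "cohort table lacks schema column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(data[[schema$id_column]])
  if (anyDuplicated(ids)) {
    stopf("validation_error", "duplicate subject ID(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  age <- data[[schema$age_column]]
  if (!is.numeric(age)) stopf("parse_error", "age column is not numeric")
  bad_age <- !is.na(age) & (age < schema$age_range[1] | age > schema$age_range[2])
  if (any(bad_age)) {
    stopf("validation_error", "age outside declared range [%g, %g] in row(s): %s",
          schema$age_range[1], schema$age_range[2],
          paste(utils::head(which(bad_age), 5), collapse = ", "))
  }
  for (col in idp_columns(schema)) {
    if (!is.numeric(data[[col]])) {
      stopf("parse_error", "IDP column '%s' is not numeric", col)
    }
  }
  data <- data[, cols, drop = FALSE]
  data[[schema$id_column]] <- ids
  rownames(data) <- NULL
  structure(list(schema = schema, data = data, truth = truth), class = "cohort")
}

#' Number of subjects in a cohort
#' @param cohort a `cohort`.
#' @return integer row count.
#' @export
n_subjects <- function(cohort) nrow(cohort$data)

#' Subject identifiers of a cohort
#' @param cohort a `cohort`.
#' @return character vector.
#' @export
subject_ids <- function(cohort) as.character(cohort$data[[cohort$schema$id_column]])

# internal: subset a cohort (and its ground truth) by row index
subset_cohort <- function(cohort, idx) {
  data <- cohort$data[idx, , drop = FALSE]
  rownames(data) <- NULL
  truth <- cohort$truth
  if (!is.null(truth)) {
    ids <- as.character(data[[cohort$schema$id_column]])
    truth <- subset_truth(truth, ids)
  }
  structure(list(schema = cohort$schema, data = data, truth = truth),
            class = "cohort")
}

#' Read a cohort table from delimited text
#'
#' The delimiter is chosen from the file extension (`.csv` comma, `.tsv`
#' tab). Empty cells and the literal `NA` are both read as missing. The table
#' is validated against `schema` and returned with columns in schema order.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema a [cohort_schema()].
#' @return a `cohort`.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stopf("io_error", "no such file: %s", path)
  sep <- sep_for_path(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  missing_cols <- setdiff(schema_columns(schema), names(df))
  if (length(missing_cols)) {
    stopf("schema_error", "file lacks schema column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  numeric_cols <- c(schema$age_column, schema$sex_column,
                    schema$education_column, idp_columns(schema),
                    schema$cognitive_columns, schema$lifestyle_columns)
  for (col in numeric_cols) {
    v <- df[[col]]
    if (is.numeric(v)) next
    v2 <- suppressWarnings(as.numeric(as.character(v)))
    bad <- which(!is.na(v) & is.na(v2))
    if (length(bad)) {
      stopf("parse_error", "non-numeric value '%s' in column '%s', row %d",
            as.character(v[bad[1]]), col, bad[1])
    }
    df[[col]] <- v2
  }
  new_cohort(df, schema)
}

#' Write a cohort to delimited text
#'
#' Floating-point values are serialized with 17 significant digits so that
#' `read_cohort(write_cohort(x))` round-trips every value exactly. Missing
#' values are written as empty cells.
#'
#' @param cohort a `cohort`.
#' @param path destination `.csv` or `.tsv` path.
#' @return `path`.
#' @export
write_cohort <- function(cohort, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("io_error", "directory does not exist: %s", dir)
  sep <- sep_for_path(path)
  write_table_precise(cohort$data, path, sep = sep)
  path
}

#' Keep only subjects complete on a set of columns
#'
#' Mirrors the study's exclusion of participants with any missing value among
#' the required variables (the nine cognitive tests and the covariates).
#' Row order is preserved and the operation is idempotent.
#'
#' @param cohort a `cohort`.
#' @param required character vector of column names that must be non-missing.
#' @return the filtered `cohort`.
#' @export
filter_complete_cases <- function(cohort, required) {
  unknown <- setdiff(required, names(cohort$data))
  if (length(unknown)) {
    stopf("schema_error", "unknown column(s): %s", paste(unknown, collapse = ", "))
  }
  keep <- stats::complete.cases(cohort$data[, required, drop = FALSE])
  subset_cohort(cohort, which(keep))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, %d IDPs in %d blocks (%s)\n",
              n_subjects(x), length(idp_columns(x$schema)),
              length(x$schema$modality_blocks),
              paste(names(x$schema$modality_blocks), collapse = ", ")))
  if (!is.null(x$truth)) {
    cat(sprintf("  synthetic ground truth: %d planted ABA, %d subtypes\n",
                sum(x$truth$aba_flag),
                nrow(x$truth$offset_directions)))
  }
  invisible(x)
}
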