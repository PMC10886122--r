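#' Cohort column schema
#'
#' A schema names every column role in a subject-level cohort table: subject
#' identifier, chronological age (years), sex (0/1 integer code), years of
#' education, the imaging-derived phenotype (IDP) columns grouped into
#' modality blocks, cognitive test scores, and lifestyle/health variables.
#' [read_cohort()] and [write_cohort()] validate and order tables against a
#' schema, and the synthetic generator emits cohorts conforming to one.
#'
#' @param modality_blocks named list of character vectors: ordered IDP column
#'   names per modality block.
#' @param id_column,age_column,sex_column,education_column column names for
#'   the core covariates.
#' @param cognitive_columns ordered character vector of cognitive test
#'   columns (nine in the default battery).
#' @param lifestyle_columns character vector of lifestyle/health columns.
#' @param log_transform_columns subset of `cognitive_columns` holding
#'   time-valued scores that are log-transformed before analysis.
#' @param qualitative_columns subset of `lifestyle_columns` stored as integer
#'   category codes and compared with chi-square tests.
#' @param age_range permissible chronological age range in years.
#' @param categorical_levels named list documenting integer code legends for
#'   categorical columns.
#' @return an object of class `cohort_schema`.
#' @seealso [ukb_schema()] for the packaged 561-IDP default.
#' @export
cohort_schema <- function(modality_blocks,
                          id_column = "subject_id",
                          age_column = "age",
                          sex_column = "sex",
                          education_column = "education_years",
                          cognitive_columns = default_cognitive_columns(),
                          lifestyle_columns = default_lifestyle_columns(),
                          log_transform_columns = c("reaction_time", "trail_making"),
                          qualitative_columns = c("walking_pace", "diabetes"),
                          age_range = c(45, 83),
                          categorical_levels = default_categorical_levels()) {
  if (!is.list(modality_blocks) || is.null(names(modality_blocks)) ||
      any(!nzchar(names(modality_blocks)))) {
    stopf("schema_error", "modality_blocks must be a named list of column names")
  }
  idp_cols <- unlist(modality_blocks, use.names = FALSE)
  roles <- c(id_column, age_column, sex_column, education_column,
             idp_cols, cognitive_columns, lifestyle_columns)
  dup <- unique(roles[duplicated(roles)])
  if (length(dup)) {
    stopf("schema_error", "column name(s) appear in two roles: %s",
          paste(dup, collapse = ", "))
  }
  if (!all(log_transform_columns %in% cognitive_columns)) {
    stopf("schema_error", "log_transform_columns must be a subset of cognitive_columns")
  }
  if (!all(qualitative_columns %in% lifestyle_columns)) {
    stopf("schema_error", "qualitative_columns must be a subset of lifestyle_columns")
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stopf("schema_error", "age_range must be (min, max) with min < max")
  }
  structure(
    list(id_column = id_column, age_column = age_column,
         sex_column = sex_column, education_column = education_column,
         modality_blocks = modality_blocks,
         cognitive_columns = cognitive_columns,
         lifestyle_columns = lifestyle_columns,
         log_transform_columns = log_transform_columns,
         qualitative_columns = qualitative_columns,
         age_range = age_range,
         categorical_levels = categorical_levels),
    class = "cohort_schema")
}

default_cognitive_columns <- function() {
  c("pairs_matching", "numeric_memory", "fluid_intelligence",
    "paired_associate_learning", "matrix_completion", "reaction_time",
    "symbol_digit", "tower_rearranging", "trail_making")
}

default_lifestyle_columns <- function() {
  c("systolic_bp", "driving_time", "grip_strength", "physical_activity",
    "walking_pace", "diabetes")
}

default_categorical_levels <- function() {
  list(sex = c(female = 0L, male = 1L),
       walking_pace = c(slow = 1L, steady = 2L, brisk = 3L),
       diabetes = c(no = 0L, yes = 1L))
}

#' Default 561-IDP multimodal schema
#'
#' Builds the packaged UK-Biobank-style schema: 207 structural IDPs (139
#' regional gray-matter volumes + 68 cortical thicknesses), 144 diffusion
#' IDPs (48 tract means each of FA, MD and ISOVF), and one partial-correlation
#' edge per pair of resting-state networks (21 networks give
#' 21 * 20 / 2 = 210 edges), for 561 IDPs in total at the defaults.
#'
#' @param n_networks number of resting-state networks; the rsfMRI block has
#'   `n_networks * (n_networks - 1) / 2` edge columns.
#' @param gm_volumes,thicknesses,tracts numbers of gray-matter volume ROIs,
#'   cortical-thickness regions, and white-matter tracts.
#' @return a [cohort_schema()] with blocks named `sMRI`, `dMRI`, `rsfMRI`.
#' @export
ukb_schema <- function(n_networks = 21L, gm_volumes = 139L,
                       thicknesses = 68L, tracts = 48L) {
  if (n_networks < 2) stopf("schema_error", "n_networks must be >= 2")
  smri <- c(sprintf("gmv_%03d", seq_len(gm_volumes)),
            sprintf("ct_%03d", seq_len(thicknesses)))
  dmri <- c(sprintf("fa_%02d", seq_len(tracts)),
            sprintf("md_%02d", seq_len(tracts)),
            sprintf("isovf_%02d", seq_len(tracts)))
  pairs <- utils::combn(n_networks, 2)
  rsfmri <- sprintf("fc_%02d_%02d", pairs[1, ], pairs[2, ])
  cohort_schema(modality_blocks = list(sMRI = smri, dMRI = dmri, rsfMRI = rsfmri))
}

# internal: schema for arbitrary block sizes (small test cohorts); reuses the
# field naming conventions where the sizes allow it
schema_for_blocks <- function(block_sizes, n_networks = NULL) {
  stopifnot(!is.null(names(block_sizes)))
  blocks <- list()
  for (m in names(block_sizes)) {
    s <- as.integer(block_sizes[[m]])
    if (s < 1) stopf("schema_error", "block size for %s must be >= 1", m)
    nm <- if (identical(m, "dMRI") && s %% 3 == 0) {
      k <- s %/% 3
      c(sprintf("fa_%02d", seq_len(k)), sprintf("md_%02d", seq_len(k)),
        sprintf("isovf_%02d", seq_len(k)))
    } else if (identical(m, "rsfMRI") && !is.null(n_networks) &&
               s == choose(n_networks, 2)) {
      pairs <- utils::combn(n_networks, 2)
      sprintf("fc_%02d_%02d", pairs[1, ], pairs[2, ])
    } else {
      sprintf("%s_%03d", tolower(m), seq_len(s))
    }
    blocks[[m]] <- nm
  }
  if (identical(sort(names(block_sizes)), sort(c("sMRI", "dMRI", "rsfMRI"))) &&
      all(unlist(block_sizes[c("sMRI", "dMRI", "rsfMRI")]) == c(207L, 144L, 210L))) {
    return(ukb_schema(n_networks = if (is.null(n_networks)) 21L else n_networks))
  }
  cohort_schema(modality_blocks = blocks)
}

#' All IDP column names of a schema, in block order
#' @param schema a [cohort_schema()].
#' @return character vector.
#' @export
idp_columns <- function(schema) {
  unlist(schema$modality_blocks, use.names = FALSE)
}

# all columns a conforming table must carry, in canonical order
schema_columns <- function(schema) {
  c(schema$id_column, schema$age_column, schema$sex_column,
    schema$education_column, idp_columns(schema),
    schema$cognitive_columns, schema$lifestyle_columns)
}

#' Serialize a schema to JSON
#' @param schema a [cohort_schema()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a schema from JSON
#' @param path a file written by [write_schema()].
#' @return a [cohort_schema()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stopf("io_error", "no such file: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_schema(modality_blocks = as.list(x$modality_blocks),
                id_column = x$id_column, age_column = x$age_column,
                sex_column = x$sex_column, education_column = x$education_column,
                cognitive_columns = x$cognitive_columns,
                lifestyle_columns = x$lifestyle_columns,
                log_transform_columns = x$log_transform_columns,
                qualitative_columns = x$qualitative_columns,
                age_range = x$age_range,
                categorical_levels = x$categorical_levels)
}

#' @export
print.cohort_schema <- function(x, ...) {
  sizes <- vapply(x$modality_blocks, length, integer(1))
  cat("cohort schema\n")
  cat("  blocks:", paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "),
      "| total IDPs:", sum(sizes), "\n")
  cat("  cognitive:", length(x$cognitive_columns),
      "| lifestyle:", length(x$lifestyle_columns),
      "| age range:", paste(x$age_range, collapse = "-"), "\n")
  invisible(x)
}
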