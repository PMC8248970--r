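# CSV input/output for samples-by-columns feature tables. The orientation
# is fixed: one row per sample, one column per feature.

#' Read a feature table from CSV
#'
#' Reads and validates a samples-by-columns CSV: a header row, a sample
#' identifier column, a batch label column, optional declared covariate and
#' outcome columns, and numeric feature columns (every remaining column).
#' UTF-8, `.` decimal. Validation fails with the offending coordinates on
#' duplicate identifiers, non-numeric feature cells, and missing values.
#'
#' @param path CSV file path.
#' @param id,batch Names of the identifier and batch columns.
#' @param covariates,outcome Optional covariate / outcome column names.
#' @return A validated tibble (row order preserved).
#' @export
read_feature_table <- function(path, id = "sample_id", batch = "batch",
                               covariates = NULL, outcome = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "tlcombat_error_io")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(id, batch, covariates, outcome)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    abort(
      paste0("Missing required column(s) in ", path, ": ",
             paste(missing_cols, collapse = ", ")),
      class = "tlcombat_error_schema"
    )
  }
  ids <- as.character(data[[id]])
  if (anyDuplicated(ids) > 0L) {
    abort(
      paste0("Duplicate sample id(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      class = "tlcombat_error_schema"
    )
  }
  feature_cols <- setdiff(names(data), required)
  for (f in feature_cols) {
    col <- data[[f]]
    if (!is.numeric(col)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      bad_row <- if (is.na(bad_row)) which(is.na(col))[1L] else bad_row
      abort(
        paste0("Non-numeric feature cell at row ", bad_row, ", column '", f,
               "' in ", path, "."),
        class = "tlcombat_error_values"
      )
    }
    if (anyNA(col) || any(!is.finite(col))) {
      bad_row <- which(is.na(col) | !is.finite(col))[1L]
      abort(
        paste0("Missing or non-finite feature value at row ", bad_row,
               ", column '", f, "' in ", path, "."),
        class = "tlcombat_error_values"
      )
    }
  }
  data
}

#' Write a feature table to CSV
#'
#' Values are printed with shortest-round-trip precision, so a write/read
#' cycle through [read_feature_table()] is lossless.
#'
#' @param data A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
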