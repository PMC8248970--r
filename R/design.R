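#' Build a covariate design matrix
#'
#' Encodes a per-sample covariate table into the numeric design matrix used
#' when estimating and removing non-batch covariate effects. Categorical
#' columns are one-hot encoded with the first level dropped; numeric columns
#' pass through unchanged. No intercept column is added: the pooled
#' per-feature mean plays the intercept role in the harmonization model.
#'
#' @param covariate_data A data frame with one row per sample, or `NULL` for
#'   the no-covariate case.
#' @param schema Optional encoding schema returned by a previous call (stored
#'   in a fitted model). When supplied, categorical columns are encoded
#'   against the stored level sets so new data maps onto the training design.
#' @return A list with `design` (an `n x p` numeric matrix, `p = 0` when
#'   there are no covariates) and `schema` (the encoding used).
#' @examples
#' build_design(data.frame(group = c("A", "A", "B", "B")))$design
#' @export
build_design <- function(covariate_data = NULL, schema = NULL) {
  if (is.null(covariate_data) || ncol(as.data.frame(covariate_data)) == 0L) {
    n <- if (is.null(covariate_data)) 0L else nrow(as.data.frame(covariate_data))
    return(list(
      design = matrix(numeric(0), nrow = n, ncol = 0L),
      schema = list()
    ))
  }
  covariate_data <- as.data.frame(covariate_data)
  if (anyNA(covariate_data)) {
    bad <- names(covariate_data)[vapply(covariate_data, anyNA, logical(1))]
    abort(
      paste0("Missing values in covariate column(s): ", paste(bad, collapse = ", ")),
      class = "tlcombat_error_covariates"
    )
  }

  derive <- is.null(schema)
  if (derive) {
    schema <- lapply(covariate_data, function(col) {
      if (is.numeric(col)) {
        list(type = "numeric")
      } else {
        list(type = "categorical", levels = levels(factor(as.character(col))))
      }
    })
    names(schema) <- names(covariate_data)
  } else {
    missing_cols <- setdiff(names(schema), names(covariate_data))
    if (length(missing_cols) > 0L) {
      abort(
        paste0("Covariate column(s) missing: ", paste(missing_cols, collapse = ", ")),
        class = "tlcombat_error_covariates"
      )
    }
  }

  blocks <- lapply(names(schema), function(nm) {
    spec <- schema[[nm]]
    col <- covariate_data[[nm]]
    if (spec$type == "numeric") {
      if (!is.numeric(col)) {
        abort(
          paste0("Covariate '", nm, "' must be numeric."),
          class = "tlcombat_error_covariates"
        )
      }
      m <- matrix(as.numeric(col), ncol = 1L, dimnames = list(NULL, nm))
    } else {
      vals <- as.character(col)
      unseen <- setdiff(unique(vals), spec$levels)
      if (length(unseen) > 0L) {
        abort(
          paste0(
            "Covariate '", nm, "' has level(s) not in the fitted schema: ",
            paste(unseen, collapse = ", ")
          ),
          class = "tlcombat_error_covariates"
        )
      }
      f <- factor(vals, levels = spec$levels)
      if (derive && nlevels(f) < 2L) {
        abort(
          paste0("Categorical covariate '", nm, "' has fewer than 2 levels."),
          class = "tlcombat_error_covariates"
        )
      }
      # one-hot, first (reference) level dropped
      keep <- spec$levels[-1L]
      m <- vapply(keep, function(lv) as.numeric(f == lv), numeric(length(f)))
      m <- matrix(m, nrow = length(f),
                  dimnames = list(NULL, paste0(nm, ":", keep)))
    }
    m
  })
  design <- do.call(cbind, blocks)
  if (!all(is.finite(design))) {
    abort("Covariate design contains non-finite values.",
          class = "tlcombat_error_covariates")
  }

  if (derive && ncol(design) > 0L) {
    const <- colnames(design)[apply(design, 2L, function(x) all(x == x[1L]))]
    if (length(const) > 0L) {
      abort(
        paste0(
          "Covariate column(s) constant after encoding: ",
          paste(const, collapse = ", ")
        ),
        class = "tlcombat_error_covariates"
      )
    }
    if (qr(cbind(1, design))$rank < ncol(design) + 1L) {
      abort("Covariate design is rank deficient after encoding.",
            class = "tlcombat_error_covariates")
    }
  }
  list(design = design, schema = schema)
}
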