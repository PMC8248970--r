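# Persistence of fitted harmonization models as versioned JSON. Floats are
# serialized as full-precision ("%.17g") decimal strings so that
# load(save(model)) reproduces every estimator bit-for-bit.

MODEL_SCHEMA_VERSION <- "1.0"

enc_vec <- function(x) {
  if (is.null(x)) return(NULL)
  list(names = as.list(names(x)), values = as.list(sprintf("%.17g", x)))
}

dec_vec <- function(o) {
  if (is.null(o)) return(NULL)
  setNames(as.numeric(unlist(o$values, use.names = FALSE)),
           as.character(unlist(o$names, use.names = FALSE)))
}

enc_mat <- function(m) {
  if (is.null(m)) return(NULL)
  list(
    dim = dim(m),
    rownames = as.list(rownames(m)),
    colnames = as.list(colnames(m)),
    values = as.list(sprintf("%.17g", m))
  )
}

dec_mat <- function(o) {
  if (is.null(o)) return(NULL)
  d <- as.integer(unlist(o$dim, use.names = FALSE))
  rn <- if (length(o$rownames)) as.character(unlist(o$rownames)) else NULL
  cn <- if (length(o$colnames)) as.character(unlist(o$colnames)) else NULL
  matrix(as.numeric(unlist(o$values, use.names = FALSE)), d[1L], d[2L],
         dimnames = list(rn, cn))
}

as_chr <- function(x) as.character(unlist(x, use.names = FALSE))

#' Save a fitted harmonization model to JSON
#'
#' Writes a versioned, human-auditable JSON document from which
#' [load_model()] reconstructs the model exactly (floats are stored as
#' full-precision decimal strings). The fit-time harmonized data is not
#' part of the persisted transform.
#'
#' @param model A `"combat_model"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "combat_model")) {
    abort("`model` must be a combat_model.", class = "tlcombat_error_input")
  }
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    tool = model$tool,
    variant = model$variant,
    eb = model$eb,
    reference_batch = model$reference_batch,
    id_col = model$id_col,
    batch_col = model$batch_col,
    covariate_cols = as.list(model$covariate_cols),
    outcome_col = model$outcome_col,
    covariate_schema = model$covariate_schema,
    non_feature_cols = as.list(model$non_feature_cols),
    batch_levels = as.list(model$batch_levels),
    n_per_batch = as.list(unname(model$n_per_batch)),
    feature_names = as.list(model$feature_names),
    alpha = enc_vec(model$alpha),
    sigma = enc_vec(model$sigma),
    beta = enc_mat(model$beta),
    ref_alpha = enc_vec(model$ref_alpha),
    ref_sigma = enc_vec(model$ref_sigma),
    gamma_hat = enc_mat(model$gamma_hat),
    delta2_hat = enc_mat(model$delta2_hat),
    gamma_star = enc_mat(model$gamma_star),
    delta2_star = enc_mat(model$delta2_star),
    converged = as.list(unname(model$converged)),
    iterations = as.list(unname(model$iterations)),
    bootstrap = if (!is.null(model$bootstrap)) {
      list(
        reps = model$bootstrap$reps,
        seed = model$bootstrap$seed,
        replicates_used = model$bootstrap$replicates_used,
        gamma_star_sd = enc_mat(model$bootstrap$gamma_star_sd)
      )
    },
    tol = sprintf("%.17g", model$tol),
    max_iter = model$max_iter
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load a fitted harmonization model from JSON
#'
#' Reads a model written by [save_model()], checking the schema version and
#' the internal consistency of the stored estimators (every registered
#' batch must have a full estimator row; posterior variances must be
#' strictly positive; feature names must be unique).
#'
#' @param path Path to a model JSON file.
#' @return A `"combat_model"`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Model file not found: ", path),
          class = "tlcombat_error_model_file")
  }
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      abort(
        paste0("Model file is truncated or not valid JSON: ", path,
               " (", conditionMessage(e), ")"),
        class = "tlcombat_error_model_file"
      )
    }
  )
  if (is.null(obj$schema_version) || obj$schema_version != MODEL_SCHEMA_VERSION) {
    abort(
      paste0("Unsupported model schema version '",
             obj$schema_version %||% "<missing>", "'; this build reads version ",
             MODEL_SCHEMA_VERSION, "."),
      class = "tlcombat_error_model_schema"
    )
  }

  batch_levels <- as_chr(obj$batch_levels)
  feature_names <- as_chr(obj$feature_names)
  if (anyDuplicated(feature_names) > 0L) {
    abort("Model file has duplicated feature names.",
          class = "tlcombat_error_model_schema")
  }
  gamma_star <- dec_mat(obj$gamma_star)
  delta2_star <- dec_mat(obj$delta2_star)
  for (nm in c("gamma_star", "delta2_star")) {
    m <- get(nm)
    missing_rows <- setdiff(batch_levels, rownames(m))
    if (length(missing_rows) > 0L) {
      abort(
        paste0("Model file is missing ", nm, " estimator row(s) for batch(es): ",
               paste(missing_rows, collapse = ", ")),
        class = "tlcombat_error_model_schema"
      )
    }
  }
  if (any(!is.finite(delta2_star)) || any(delta2_star <= 0)) {
    abort("Model file has non-positive posterior variances.",
          class = "tlcombat_error_model_schema")
  }

  schema <- lapply(obj$covariate_schema, function(s) {
    out <- list(type = s$type)
    if (!is.null(s$levels)) out$levels <- as_chr(s$levels)
    out
  })

  model <- structure(
    list(
      version = as.character(obj$schema_version),
      tool = list(package = as.character(obj$tool$package),
                  version = as.character(obj$tool$version)),
      variant = as.character(obj$variant),
      eb = as.character(obj$eb),
      reference_batch = if (is.null(obj$reference_batch)) NULL else
        as.character(obj$reference_batch),
      id_col = as.character(obj$id_col),
      batch_col = as.character(obj$batch_col),
      covariate_cols = if (length(obj$covariate_cols)) as_chr(obj$covariate_cols)
        else NULL,
      outcome_col = if (is.null(obj$outcome_col)) NULL else
        as.character(obj$outcome_col),
      covariate_schema = schema,
      non_feature_cols = as_chr(obj$non_feature_cols),
      batch_levels = batch_levels,
      n_per_batch = setNames(as.integer(unlist(obj$n_per_batch)), batch_levels),
      feature_names = feature_names,
      alpha = dec_vec(obj$alpha),
      sigma = dec_vec(obj$sigma),
      beta = dec_mat(obj$beta),
      ref_alpha = dec_vec(obj$ref_alpha),
      ref_sigma = dec_vec(obj$ref_sigma),
      gamma_hat = dec_mat(obj$gamma_hat),
      delta2_hat = dec_mat(obj$delta2_hat),
      gamma_star = gamma_star,
      delta2_star = delta2_star,
      converged = setNames(as.logical(unlist(obj$converged)), batch_levels),
      iterations = setNames(as.integer(unlist(obj$iterations)), batch_levels),
      bootstrap = if (!is.null(obj$bootstrap)) {
        list(
          reps = as.integer(obj$bootstrap$reps),
          seed = as.integer(obj$bootstrap$seed),
          replicates_used = as.integer(obj$bootstrap$replicates_used),
          gamma_star_sd = dec_mat(obj$bootstrap$gamma_star_sd)
        )
      },
      tol = as.numeric(obj$tol),
      max_iter = as.integer(obj$max_iter)
    ),
    class = "combat_model"
  )
  model
}
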