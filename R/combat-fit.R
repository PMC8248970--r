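#' Fit a ComBat-family harmonization model
#'
#' Fits the empirical-Bayes location-scale harmonization model to a
#' samples-by-columns table and harmonizes it. Four variants are available:
#'
#' * `"combat"` — standard ComBat: per-batch additive and multiplicative
#'   effects are estimated on the standardized scale, shrunk toward
#'   batch-level priors, removed, and every sample is mapped to the pooled
#'   grand mean and variance.
#' * `"m-combat"` — as above, but all samples are rescaled to the mean and
#'   variance of a chosen `reference_batch`, preserving the physical meaning
#'   of features such as volumes or uptake values.
#' * `"b-combat"` / `"bm-combat"` — bootstrap-stabilized counterparts: the
#'   whole estimation stage is rerun on stratified within-batch resamples
#'   and the estimators are averaged over replicates (Monte-Carlo mean)
#'   before the original data is adjusted.
#'
#' The fitted model stores everything needed to harmonize new samples from
#' the same batches later with [combat_apply()], without re-fitting on the
#' pooled data.
#'
#' @param data A data frame with one row per sample: an identifier column, a
#'   batch/center label column, optional covariate and outcome columns, and
#'   numeric feature columns.
#' @param batch,id Names of the batch-label and sample-identifier columns.
#' @param covariates Optional character vector of covariate column names
#'   whose (non-batch) effects are preserved through harmonization.
#' @param outcome Optional name of an outcome column to exclude from the
#'   feature set (it is carried through untouched).
#' @param features Optional character vector of feature column names;
#'   defaults to every remaining numeric column.
#' @param variant One of `"combat"`, `"m-combat"`, `"b-combat"`,
#'   `"bm-combat"`.
#' @param eb Empirical-Bayes mode: `"parametric"` (Normal / Inverse-Gamma
#'   priors), `"nonparametric"` (leave-one-out likelihood-weighted
#'   posterior), or `"none"` (no shrinkage; raw batch moments are removed).
#' @param reference_batch Reference batch id; required for the M variants.
#' @param bootstrap_reps Number of bootstrap replicates for the B variants
#'   (default 100).
#' @param seed RNG seed for the bootstrap resampling; required for the B
#'   variants and recorded in the model.
#' @param tol,max_iter Convergence controls for the parametric posterior
#'   fixed-point iteration.
#' @param drop_constant If `TRUE`, constant feature columns are dropped with
#'   a message instead of raising an error.
#' @return An object of class `"combat_model"`. The harmonized training
#'   data is available as `$harmonized` (a tibble shaped like `data`).
#' @seealso [combat_apply()] to harmonize new samples, [save_model()] /
#'   [load_model()] for persistence, [harmonization_diagnostics()] to verify
#'   the result.
#' @examples
#' sim <- simulate_batch_data(
#'   n_features = 20, batch_sizes = c(A = 30, B = 30), seed = 1
#' )
#' fit <- combat_fit(sim$data, batch = "batch", outcome = "outcome")
#' fit$harmonized
#' @export
combat_fit <- function(data, batch = "batch", id = "sample_id",
                       covariates = NULL, outcome = NULL, features = NULL,
                       variant = c("combat", "m-combat", "b-combat", "bm-combat"),
                       eb = c("parametric", "nonparametric", "none"),
                       reference_batch = NULL, bootstrap_reps = 100L,
                       seed = NULL, tol = 1e-4, max_iter = 200L,
                       drop_constant = FALSE) {
  variant <- match.arg(variant)
  eb <- match.arg(eb)
  is_m <- variant %in% c("m-combat", "bm-combat")
  is_b <- variant %in% c("b-combat", "bm-combat")

  parts <- partition_table(data, id = id, batch = batch,
                           covariates = covariates, outcome = outcome,
                           features = features)
  Y <- parts$Y
  bf <- factor(parts$batch, levels = unique(parts$batch))
  check_batch_sizes(parts$batch)

  if (is_m) {
    if (is.null(reference_batch)) {
      abort("`reference_batch` is required for the M variants.",
            class = "tlcombat_error_config")
    }
    if (!reference_batch %in% levels(bf)) {
      abort(
        paste0("Unknown reference batch '", reference_batch, "'. Batches: ",
               paste(levels(bf), collapse = ", ")),
        class = "tlcombat_error_unknown_batch"
      )
    }
  } else if (!is.null(reference_batch)) {
    abort("`reference_batch` only applies to the M variants.",
          class = "tlcombat_error_config")
  }
  if (is_b && is.null(seed)) {
    abort("A `seed` is required for the bootstrap variants.",
          class = "tlcombat_error_config")
  }

  if (drop_constant) {
    const <- colnames(Y)[apply(Y, 2L, function(x) all(x == x[1L]))]
    if (length(const) > 0L) {
      inform(paste0("Dropping constant feature(s): ",
                    paste(const, collapse = ", ")))
      Y <- Y[, setdiff(colnames(Y), const), drop = FALSE]
      parts$feature_names <- colnames(Y)
      if (ncol(Y) == 0L) {
        abort("All features are constant.", class = "tlcombat_error_constant_feature")
      }
    }
  }

  enc <- build_design(parts$covariate_data)
  design <- enc$design
  if (ncol(design) == 0L) design <- matrix(numeric(0), nrow(Y), 0L)

  stages <- fit_stages(Y, bf, design, eb = eb, tol = tol, max_iter = max_iter)

  boot <- NULL
  if (is_b) {
    boot <- bootstrap_estimates(
      Y, bf, design,
      eb = eb, reps = bootstrap_reps, seed = seed,
      tol = tol, max_iter = max_iter
    )
  }

  use <- if (is_b) boot$avg else list(
    alpha = stages$globals$alpha,
    sigma = stages$globals$sigma,
    beta = stages$globals$beta,
    per_batch_alpha = stages$globals$per_batch_alpha,
    per_batch_sigma = stages$globals$per_batch_sigma,
    gamma_star = stages$post$gamma_star,
    delta2_star = stages$post$delta2_star
  )

  model <- structure(
    list(
      version = "1.0",
      tool = list(package = "tlcombat",
                  version = as.character(packageVersion("tlcombat"))),
      variant = variant,
      eb = eb,
      reference_batch = reference_batch,
      id_col = id,
      batch_col = batch,
      covariate_cols = covariates,
      outcome_col = outcome,
      covariate_schema = enc$schema,
      non_feature_cols = setdiff(names(data), colnames(Y)),
      batch_levels = levels(bf),
      n_per_batch = setNames(as.integer(table(bf)[levels(bf)]), levels(bf)),
      feature_names = colnames(Y),
      alpha = use$alpha,
      sigma = use$sigma,
      beta = use$beta,
      ref_alpha = if (is_m) use$per_batch_alpha[reference_batch, ] else NULL,
      ref_sigma = if (is_m) use$per_batch_sigma[reference_batch, ] else NULL,
      gamma_hat = stages$est$gamma_hat,
      delta2_hat = stages$est$delta2_hat,
      gamma_star = use$gamma_star,
      delta2_star = use$delta2_star,
      converged = stages$post$converged,
      iterations = stages$post$iterations,
      bootstrap = if (is_b) {
        list(reps = as.integer(bootstrap_reps), seed = as.integer(seed),
             replicates_used = boot$replicates_used,
             gamma_star_sd = boot$gamma_star_sd)
      } else {
        NULL
      },
      tol = as.numeric(tol),
      max_iter = as.integer(max_iter)
    ),
    class = "combat_model"
  )
  model$harmonized <- combat_apply(model, data)
  model
}

# Run the non-bootstrap estimation chain once:
# globals -> Z -> batch effects -> (hyper +) posterior.
fit_stages <- function(Y, bf, design, eb, tol, max_iter) {
  globals <- estimate_global(Y, bf, design)
  Z <- standardize(Y, globals, design)
  est <- estimate_batch_effects(Z, bf)
  post <- switch(
    eb,
    parametric = eb_posterior_parametric(Z, bf, est,
                                         estimate_hyperparameters(est),
                                         tol = tol, max_iter = max_iter),
    nonparametric = eb_posterior_nonparametric(Z, bf, est),
    none = {
      if (any(est$delta2_hat <= 0)) {
        abort(
          "Shrinkage-off mode needs positive within-batch variance for every feature.",
          class = "tlcombat_error_degenerate"
        )
      }
      structure(
        list(
          gamma_star = est$gamma_hat,
          delta2_star = est$delta2_hat,
          converged = setNames(rep(TRUE, length(est$batch_levels)),
                               est$batch_levels),
          iterations = setNames(integer(length(est$batch_levels)),
                                est$batch_levels),
          batch_levels = est$batch_levels
        ),
        class = "combat_posterior"
      )
    }
  )
  list(globals = globals, Z = Z, est = est, post = post)
}

#' Harmonize samples with a fitted model
#'
#' Applies a fitted harmonization transform to a table of samples from
#' batches registered in the model — the transfer-learning mode: new,
#' previously unseen samples from known centers are standardized with the
#' *stored* pooled estimates and adjusted with the *stored* posterior batch
#' estimators; nothing is re-estimated on the new data. Applying the model
#' to its own training data reproduces the fit-time harmonized output.
#'
#' Samples from batches absent at fit time are rejected: there is no direct
#' way to apply a fitted transform to an entirely new center.
#'
#' @param model A `"combat_model"` from [combat_fit()] or [load_model()].
#' @param data A data frame shaped like the training data: same identifier,
#'   batch, covariate, and feature columns (feature order may differ; they
#'   are realigned by name). A single new sample is fine.
#' @return A tibble: `data` with its feature columns replaced by their
#'   harmonized values; all other columns are passed through untouched.
#' @examples
#' sim <- simulate_batch_data(
#'   n_features = 12, batch_sizes = c(A = 40, B = 40), seed = 3
#' )
#' parts <- split_holdout(sim$data, test_fraction = 0.25, seed = 4)
#' fit <- combat_fit(parts$train, outcome = "outcome")
#' combat_apply(fit, parts$test)
#' @export
combat_apply <- function(model, data) {
  if (!inherits(model, "combat_model")) {
    abort("`model` must be a combat_model.", class = "tlcombat_error_input")
  }
  parts <- partition_table(
    data,
    id = model$id_col, batch = model$batch_col,
    covariates = model$covariate_cols,
    outcome = if (!is.null(model$outcome_col) &&
                  model$outcome_col %in% names(data)) model$outcome_col else NULL
  )
  got <- setdiff(parts$feature_names, model$non_feature_cols)
  want <- model$feature_names
  if (!setequal(got, want)) {
    missing <- setdiff(want, got)
    extra <- setdiff(got, want)
    abort(
      paste0(
        "Feature columns do not match the fitted model.",
        if (length(missing)) paste0(" Missing: ", paste(missing, collapse = ", "), "."),
        if (length(extra)) paste0(" Unexpected: ", paste(extra, collapse = ", "), ".")
      ),
      class = "tlcombat_error_features"
    )
  }
  unknown <- setdiff(unique(parts$batch), model$batch_levels)
  if (length(unknown) > 0L) {
    abort(
      paste0(
        "Batch label(s) not registered in the model: ",
        paste(unknown, collapse = ", "),
        ". Samples from new centers cannot be harmonized with a stored transform."
      ),
      class = "tlcombat_error_unknown_batch"
    )
  }

  Y <- parts$Y[, want, drop = FALSE]
  design <- build_design(parts$covariate_data, schema = model$covariate_schema)$design
  if (ncol(design) == 0L) design <- matrix(numeric(0), nrow(Y), 0L)

  globals <- structure(
    list(
      alpha = model$alpha, sigma = model$sigma, beta = model$beta,
      batch_levels = model$batch_levels, feature_names = want
    ),
    class = "combat_globals"
  )
  Z <- standardize(Y, globals, design)
  post <- list(
    gamma_star = model$gamma_star,
    delta2_star = model$delta2_star,
    batch_levels = model$batch_levels
  )
  is_m <- model$variant %in% c("m-combat", "bm-combat")
  adjusted <- adjust_to_target(
    Z, post, globals, design, parts$batch,
    target_mean = if (is_m) model$ref_alpha else model$alpha,
    target_sd = if (is_m) model$ref_sigma else model$sigma
  )

  out <- as_tibble(data)
  out[, want] <- adjusted[, want, drop = FALSE]
  out
}

#' @export
print.combat_model <- function(x, ...) {
  cat("ComBat harmonization model (", x$variant, ", EB: ", x$eb, ")\n", sep = "")
  cat("  batches: ",
      paste0(x$batch_levels, " (n=", x$n_per_batch, ")", collapse = ", "),
      "\n", sep = "")
  cat("  features: ", length(x$feature_names), "\n", sep = "")
  if (!is.null(x$reference_batch)) {
    cat("  reference batch: ", x$reference_batch, "\n", sep = "")
  }
  if (!is.null(x$bootstrap)) {
    cat("  bootstrap: ", x$bootstrap$replicates_used, "/", x$bootstrap$reps,
        " replicates (seed ", x$bootstrap$seed, ")\n", sep = "")
  }
  if (!all(x$converged)) {
    cat("  note: posterior iteration did not converge for: ",
        paste(names(x$converged)[!x$converged], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
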