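# broom-style accessors for fitted models and diagnostics reports.

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a fitted harmonization model
#'
#' One row per batch-feature pair with the raw batch-effect estimates and
#' their empirical-Bayes posteriors.
#'
#' @param x A `"combat_model"`.
#' @param ... Unused.
#' @return A tibble with columns `batch`, `feature`, `gamma_hat`,
#'   `delta2_hat`, `gamma_star`, `delta2_star`.
#' @export
tidy.combat_model <- function(x, ...) {
  tidyr::expand_grid(batch = x$batch_levels, feature = x$feature_names) |>
    dplyr::mutate(
      gamma_hat = as.vector(t(x$gamma_hat)),
      delta2_hat = as.vector(t(x$delta2_hat)),
      gamma_star = as.vector(t(x$gamma_star)),
      delta2_star = as.vector(t(x$delta2_star))
    )
}

#' Glance at a fitted harmonization model
#'
#' @param x A `"combat_model"`.
#' @param ... Unused.
#' @return A one-row tibble summarizing the fit configuration and scale.
#' @export
glance.combat_model <- function(x, ...) {
  tibble(
    variant = x$variant,
    eb = x$eb,
    n_batches = length(x$batch_levels),
    n_samples = sum(x$n_per_batch),
    n_features = length(x$feature_names),
    n_covariate_terms = nrow(x$beta),
    reference_batch = x$reference_batch %||% NA_character_,
    bootstrap_reps = if (is.null(x$bootstrap)) NA_integer_ else
      x$bootstrap$replicates_used,
    converged = all(x$converged)
  )
}

#' Harmonize data with a fitted model (broom-style)
#'
#' `augment()` on a harmonization model applies the stored transform to
#' `data` via [combat_apply()]; with `data = NULL` it returns the fit-time
#' harmonized training table.
#'
#' @param x A `"combat_model"`.
#' @param data Optional new data frame of samples from registered batches.
#' @param ... Unused.
#' @return A tibble of harmonized samples.
#' @export
augment.combat_model <- function(x, data = NULL, ...) {
  if (is.null(data)) x$harmonized else combat_apply(x, data)
}

#' @rdname harmonization_diagnostics
#' @param x A `"combat_diagnostics"` report.
#' @param ... Unused.
#' @export
tidy.combat_diagnostics <- function(x, ...) {
  dplyr::left_join(x$anova, x$cov, by = "feature")
}

#' @rdname harmonization_diagnostics
#' @export
glance.combat_diagnostics <- function(x, ...) {
  tibble(
    n_features = nrow(x$anova),
    fraction_significant = x$fraction_significant,
    alpha = x$alpha,
    cov_aggregate = x$cov_aggregate,
    pc1_var_explained = x$pca$var_explained[1L],
    pc2_var_explained = x$pca$var_explained[2L]
  )
}
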