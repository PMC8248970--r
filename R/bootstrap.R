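# Bootstrap-stabilized estimation for the B-ComBat / BM-ComBat variants:
# the full estimation chain is rerun on stratified within-batch resamples
# and every estimator is averaged over replicates (Monte-Carlo mean). The
# averaged estimators are then applied to the ORIGINAL data through the
# usual adjustment step.

#' Bootstrap-averaged harmonization estimators
#'
#' Reruns the estimation stage (pooled location/scale, covariate
#' coefficients, and empirical-Bayes posterior batch estimators) on `reps`
#' stratified within-batch resamples of the data, and returns the per-entry
#' Monte-Carlo means. Resampling is with replacement and preserves every
#' batch's sample size. A replicate whose resample produces a degenerate
#' (zero-variance) feature is redrawn a bounded number of times and then
#' skipped with a warning; `replicates_used` records the effective count.
#'
#' @param Y Numeric matrix, samples in rows, features in columns.
#' @param batch Per-sample batch labels.
#' @param design Covariate design matrix from [build_design()].
#' @param eb Empirical-Bayes mode (see [combat_fit()]).
#' @param reps Number of bootstrap replicates (B >= 1).
#' @param seed RNG seed; the caller's random-number stream is left
#'   untouched.
#' @param tol,max_iter Posterior fixed-point controls.
#' @param .resample Internal hook: a `function(rows_of_batch, n)` returning
#'   resampled row indices. The default samples with replacement.
#' @return A list with `avg` (averaged `alpha`, `sigma`, `beta`,
#'   `per_batch_alpha`, `per_batch_sigma`, `gamma_star`, `delta2_star`),
#'   `gamma_star_sd` (across-replicate standard deviation), and
#'   `replicates_used`.
#' @export
bootstrap_estimates <- function(Y, batch, design = NULL, eb = "parametric",
                                reps = 100L, seed, tol = 1e-4,
                                max_iter = 200L, .resample = NULL) {
  reps <- as.integer(reps)
  if (reps < 1L) {
    abort("`reps` must be at least 1.", class = "tlcombat_error_config")
  }
  Y <- as.matrix(Y)
  bf <- if (is.factor(batch)) droplevels(batch) else factor(batch, levels = unique(batch))
  if (is.null(design)) design <- matrix(numeric(0), nrow = nrow(Y), ncol = 0L)
  rows_by_batch <- split(seq_len(nrow(Y)), bf)
  resample <- .resample %||% function(rows, n) sample(rows, n, replace = TRUE)

  sums <- NULL
  sq_gamma <- NULL
  used <- 0L
  skipped <- 0L
  n_unconverged <- 0L

  add <- function(acc, x) if (is.null(acc)) x else acc + x

  with_preserved_seed(seed, {
    for (k in seq_len(reps)) {
      rep_fit <- NULL
      for (try in 1:10) {
        idx <- unlist(lapply(rows_by_batch, function(rows) {
          resample(rows, length(rows))
        }), use.names = FALSE)
        rep_fit <- tryCatch(
          withCallingHandlers(
            fit_stages(Y[idx, , drop = FALSE], bf[idx],
                       design[idx, , drop = FALSE],
                       eb = eb, tol = tol, max_iter = max_iter),
            tlcombat_warning_no_convergence = function(w) {
              n_unconverged <<- n_unconverged + 1L
              invokeRestart("muffleWarning")
            }
          ),
          tlcombat_error_constant_feature = function(e) NULL,
          tlcombat_error_degenerate = function(e) NULL
        )
        if (!is.null(rep_fit)) break
      }
      if (is.null(rep_fit)) {
        skipped <- skipped + 1L
        next
      }
      used <- used + 1L
      g <- rep_fit$globals
      p <- rep_fit$post
      sums <- list(
        alpha = add(sums$alpha, g$alpha),
        sigma = add(sums$sigma, g$sigma),
        beta = add(sums$beta, g$beta),
        per_batch_alpha = add(sums$per_batch_alpha, g$per_batch_alpha),
        per_batch_sigma = add(sums$per_batch_sigma, g$per_batch_sigma),
        gamma_star = add(sums$gamma_star, p$gamma_star),
        delta2_star = add(sums$delta2_star, p$delta2_star)
      )
      sq_gamma <- add(sq_gamma, p$gamma_star^2)
    }
  })

  if (used == 0L) {
    abort("Every bootstrap replicate was degenerate; cannot average.",
          class = "tlcombat_error_bootstrap")
  }
  if (skipped > 0L) {
    warn(
      paste0(skipped, " bootstrap replicate(s) skipped after repeated ",
             "degenerate resamples."),
      class = "tlcombat_warning_bootstrap_skip"
    )
  }
  if (n_unconverged > 0L) {
    warn(
      paste0("Posterior iteration hit `max_iter` in ", n_unconverged,
             " bootstrap batch fits."),
      class = "tlcombat_warning_no_convergence"
    )
  }

  avg <- lapply(sums, function(x) x / used)
  gamma_var <- sq_gamma / used - avg$gamma_star^2
  gamma_var[gamma_var < 0] <- 0
  sd_scale <- if (used > 1L) used / (used - 1L) else NA_real_
  list(
    avg = avg,
    gamma_star_sd = sqrt(gamma_var * sd_scale),
    replicates_used = used
  )
}
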