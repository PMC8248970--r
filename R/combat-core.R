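# Estimation stages of the empirical-Bayes location-scale harmonization
# model. All stage functions work on numeric matrices with samples in rows
# and features in columns; `combat_fit()` is the data-frame front end.

#' Pooled feature-wise location/scale and covariate coefficients
#'
#' Fits, feature by feature, an ordinary least-squares model with one mean
#' term per batch plus any covariate terms, and derives the pooled
#' standardization parameters: the sample-size-weighted grand mean
#' \eqn{\hat\alpha_g}, the pooled population residual standard deviation
#' \eqn{\hat\sigma_g} (denominator `n`), and the covariate
#' coefficients \eqn{\hat\beta_g}. Per-batch means and population standard
#' deviations of the covariate-residualized features are also returned; the
#' reference-batch variants use them as rescaling targets.
#'
#' @param Y Numeric matrix, samples in rows, features in columns.
#' @param batch Character or factor vector of per-sample batch labels.
#' @param design Covariate design matrix from [build_design()] (may have
#'   zero columns).
#' @return A list of class `"combat_globals"` with elements `alpha`, `sigma`,
#'   `beta`, `per_batch_alpha`, `per_batch_sigma`, `batch_levels`,
#'   `n_per_batch`, `feature_names`.
#' @export
estimate_global <- function(Y, batch, design = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  G <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("feature_", seq_len(G))
  bf <- if (is.factor(batch)) droplevels(batch) else factor(batch, levels = unique(batch))
  if (length(bf) != n) {
    abort("`batch` length must equal the number of samples.",
          class = "tlcombat_error_input")
  }
  if (is.null(design)) design <- matrix(numeric(0), nrow = n, ncol = 0L)
  if (nrow(design) != n) {
    abort("Covariate design is not row-aligned with `Y`.",
          class = "tlcombat_error_input")
  }

  batch_ind <- vapply(levels(bf), function(b) as.numeric(bf == b), numeric(n))
  X <- cbind(batch_ind, design)
  fit <- stats::lm.fit(X, Y)
  if (fit$rank < ncol(X)) {
    abort("Batch-plus-covariate design is rank deficient.",
          class = "tlcombat_error_covariates")
  }
  coefs <- fit$coefficients
  if (!is.matrix(coefs)) { # single-feature response drops to a vector
    coefs <- matrix(coefs, ncol(X), ncol(Y))
  }
  dimnames(coefs) <- list(colnames(X), colnames(Y))
  n_i <- as.integer(table(bf)[levels(bf)])
  batch_means <- coefs[seq_along(levels(bf)), , drop = FALSE]
  alpha <- as.numeric(crossprod(batch_means, n_i) / n)
  beta <- coefs[-seq_along(levels(bf)), , drop = FALSE]
  res <- fit$residuals
  if (!is.matrix(res)) res <- matrix(res, nrow(Y), ncol(Y))
  # population (denominator n) pooled residual SD: the same convention as
  # the per-batch variances, which makes the no-shrinkage adjustment an
  # exact inverse of standardization on a single batch
  sigma <- sqrt(colSums(res^2) / n)
  names(alpha) <- names(sigma) <- colnames(Y)

  degenerate <- colnames(Y)[!is.finite(sigma) | sigma <= 1e-10 * (abs(alpha) + 1)]
  if (length(degenerate) > 0L) {
    abort(
      paste0(
        "Zero-variance feature(s): ", paste(degenerate, collapse = ", "),
        ". Drop them before fitting (or use `drop_constant = TRUE`)."
      ),
      class = "tlcombat_error_constant_feature"
    )
  }

  resid_cov <- Y - design %*% beta
  gm <- group_moments(resid_cov, bf)

  structure(
    list(
      alpha = alpha,
      sigma = sigma,
      beta = beta,
      per_batch_alpha = gm$mean,
      per_batch_sigma = sqrt(gm$var),
      batch_levels = levels(bf),
      n_per_batch = n_i,
      feature_names = colnames(Y)
    ),
    class = "combat_globals"
  )
}

#' Standardize a feature matrix against pooled estimates
#'
#' Computes \eqn{Z_{ijg} = (Y_{ijg} - \hat\alpha_g - X_j\hat\beta_g) /
#' \hat\sigma_g}: features are centred on the pooled mean (and any covariate
#' effect) and scaled to the pooled residual standard deviation, so that
#' batch effects can be estimated on a common scale across features.
#'
#' @param Y Numeric matrix, samples in rows, features in columns (names must
#'   match those the globals were fitted on).
#' @param globals A `"combat_globals"` object from [estimate_global()].
#' @param design Covariate design matrix row-aligned with `Y`.
#' @return The standardized matrix `Z`, same shape and dimnames as `Y`.
#' @export
standardize <- function(Y, globals, design = NULL) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("feature_", seq_len(ncol(Y)))
  if (!setequal(colnames(Y), globals$feature_names)) {
    extra <- setdiff(colnames(Y), globals$feature_names)
    missing <- setdiff(globals$feature_names, colnames(Y))
    abort(
      paste0(
        "Feature names do not match the fitted estimates.",
        if (length(missing)) paste0(" Missing: ", paste(missing, collapse = ", "), "."),
        if (length(extra)) paste0(" Unexpected: ", paste(extra, collapse = ", "), ".")
      ),
      class = "tlcombat_error_features"
    )
  }
  Y <- Y[, globals$feature_names, drop = FALSE]
  if (is.null(design)) design <- matrix(numeric(0), nrow = nrow(Y), ncol = 0L)
  shift <- design %*% globals$beta
  Z <- sweep(sweep(Y - shift, 2L, globals$alpha, "-"), 2L, globals$sigma, "/")
  Z
}

#' Per-batch moments of the standardized data
#'
#' For each batch and feature, the batch-effect point estimates: the batch
#' mean \eqn{\hat\gamma_{ig}} and the batch variance
#' \eqn{\hat\delta^2_{ig}} of the standardized values (variance denominator
#' `n_i`, matching the conjugate posterior).
#'
#' @param Z Standardized matrix from [standardize()].
#' @param batch Per-sample batch labels.
#' @return A list of class `"combat_batch_effects"` with `gamma_hat` and
#'   `delta2_hat` (batches x features matrices), `n_per_batch`, and
#'   `batch_levels`.
#' @export
estimate_batch_effects <- function(Z, batch) {
  Z <- as.matrix(Z)
  bf <- if (is.factor(batch)) droplevels(batch) else factor(batch, levels = unique(batch))
  counts <- table(bf)
  singletons <- names(counts)[counts < 2L]
  if (length(singletons) > 0L) {
    abort(
      paste0("Batch(es) with fewer than 2 samples: ",
             paste(singletons, collapse = ", ")),
      class = "tlcombat_error_batch_size"
    )
  }
  gm <- group_moments(Z, bf)
  structure(
    list(
      gamma_hat = gm$mean,
      delta2_hat = gm$var,
      n_per_batch = gm$n,
      batch_levels = levels(bf)
    ),
    class = "combat_batch_effects"
  )
}

#' Empirical prior hyperparameters by the method of moments
#'
#' Estimates, per batch, the hyperparameters of the conjugate priors
#' \eqn{\gamma_{ig} \sim N(\bar\gamma_i, \bar\tau^2_i)} and
#' \eqn{\delta^2_{ig} \sim \mathrm{InvGamma}(\bar\lambda_i, \bar\theta_i)}
#' by matching moments across features: \eqn{\bar\gamma_i} and
#' \eqn{\bar\tau^2_i} are the mean and variance over features of
#' \eqn{\hat\gamma_{ig}}; with `M` and `V` the mean and variance over
#' features of \eqn{\hat\delta^2_{ig}}, \eqn{\bar\lambda_i = M^2/V + 2} and
#' \eqn{\bar\theta_i = M(\bar\lambda_i - 1)}. When `V = 0` (all batch
#' variances identical) the inverse-gamma prior is degenerate and scale
#' shrinkage is disabled for that batch (`scale_shrinkage = FALSE`).
#'
#' @param est A `"combat_batch_effects"` object.
#' @return A list of class `"combat_hyperparameters"` with per-batch vectors
#'   `gamma_bar`, `tau2_bar`, `lambda_bar`, `theta_bar`, `scale_shrinkage`.
#' @export
estimate_hyperparameters <- function(est) {
  if (ncol(est$gamma_hat) < 2L) {
    abort("At least 2 features are needed to estimate empirical priors.",
          class = "tlcombat_error_input")
  }
  gamma_bar <- rowMeans(est$gamma_hat)
  tau2_bar <- apply(est$gamma_hat, 1L, var)
  M <- rowMeans(est$delta2_hat)
  V <- apply(est$delta2_hat, 1L, var)
  lambda_bar <- M^2 / V + 2
  theta_bar <- M * (lambda_bar - 1)
  # V numerically indistinguishable from 0 (all batch variances identical)
  # means a degenerate inverse-gamma prior: disable scale shrinkage
  ok <- is.finite(lambda_bar) & V > M^2 * 1e-12 & lambda_bar > 2
  lambda_bar[!ok] <- NA_real_
  theta_bar[!ok] <- NA_real_
  structure(
    list(
      gamma_bar = gamma_bar,
      tau2_bar = tau2_bar,
      lambda_bar = lambda_bar,
      theta_bar = theta_bar,
      scale_shrinkage = ok,
      batch_levels = est$batch_levels
    ),
    class = "combat_hyperparameters"
  )
}

#' Parametric empirical-Bayes posterior batch-effect estimators
#'
#' Solves, per batch and feature, the coupled conditional-posterior-mean
#' system
#' \deqn{\gamma^*_{ig} = \frac{n_i\bar\tau^2_i\hat\gamma_{ig} +
#'   \delta^{2*}_{ig}\bar\gamma_i}{n_i\bar\tau^2_i + \delta^{2*}_{ig}},
#'   \quad
#'   \delta^{2*}_{ig} = \frac{\bar\theta_i + \tfrac12\sum_j (Z_{ijg} -
#'   \gamma^*_{ig})^2}{n_i/2 + \bar\lambda_i - 1}}
#' by fixed-point iteration initialized at the raw batch moments, stopping
#' when the maximum relative change falls below `tol` or after `max_iter`
#' sweeps (non-convergence is recorded and warned about, not an error).
#' Batches whose inverse-gamma prior was degenerate keep their raw batch
#' variances (\eqn{\delta^{2*} = \hat\delta^2}) and get the closed-form
#' location posterior.
#'
#' @param Z Standardized matrix.
#' @param batch Per-sample batch labels.
#' @param est A `"combat_batch_effects"` object for `Z`.
#' @param hyper A `"combat_hyperparameters"` object.
#' @param tol Relative-change convergence tolerance (default `1e-4`).
#' @param max_iter Maximum fixed-point sweeps (default 200).
#' @return A list of class `"combat_posterior"` with `gamma_star`,
#'   `delta2_star` (batches x features, `delta2_star > 0`), and per-batch
#'   `converged` / `iterations`.
#' @export
eb_posterior_parametric <- function(Z, batch, est, hyper,
                                    tol = 1e-4, max_iter = 200L) {
  stopifnot(tol > 0, max_iter >= 1L)
  Z <- as.matrix(Z)
  bf <- factor(as.character(batch), levels = est$batch_levels)
  B <- length(est$batch_levels)
  gamma_star <- est$gamma_hat
  delta2_star <- est$delta2_hat
  converged <- rep(TRUE, B)
  iterations <- integer(B)
  names(converged) <- names(iterations) <- est$batch_levels

  for (i in seq_len(B)) {
    b <- est$batch_levels[i]
    Zi <- Z[bf == b, , drop = FALSE]
    n_i <- nrow(Zi)
    S1 <- colSums(Zi)
    S2 <- colSums(Zi^2)
    g_hat <- est$gamma_hat[i, ]
    d_hat <- est$delta2_hat[i, ]
    g_bar <- hyper$gamma_bar[i]
    t2 <- hyper$tau2_bar[i]

    if (!hyper$scale_shrinkage[i]) {
      if (any(d_hat <= 0)) {
        abort(
          paste0("Batch '", b, "': degenerate scale prior with a ",
                 "zero-variance feature; posterior variance undefined."),
          class = "tlcombat_error_degenerate"
        )
      }
      gamma_star[i, ] <- (n_i * t2 * g_hat + d_hat * g_bar) / (n_i * t2 + d_hat)
      delta2_star[i, ] <- d_hat
      iterations[i] <- 0L
      next
    }

    lam <- hyper$lambda_bar[i]
    th <- hyper$theta_bar[i]
    g_old <- g_hat
    d_old <- d_hat
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (n_i * t2 * g_hat + d_old * g_bar) / (n_i * t2 + d_old)
      ss <- S2 - 2 * g_new * S1 + n_i * g_new^2
      d_new <- (th + 0.5 * ss) / (n_i / 2 + lam - 1)
      change <- max(
        abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
        abs(d_new - d_old) / pmax(abs(d_old), 1e-8)
      )
      g_old <- g_new
      d_old <- d_new
      if (change < tol || it >= max_iter) break
    }
    if (it >= max_iter && change >= tol) {
      converged[i] <- FALSE
      warn(
        paste0("Posterior fixed-point did not converge for batch '", b,
               "' within ", max_iter, " iterations."),
        class = "tlcombat_warning_no_convergence"
      )
    }
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- d_old
    iterations[i] <- it
  }

  structure(
    list(
      gamma_star = gamma_star,
      delta2_star = delta2_star,
      converged = converged,
      iterations = iterations,
      batch_levels = est$batch_levels
    ),
    class = "combat_posterior"
  )
}

#' Non-parametric empirical-Bayes posterior batch-effect estimators
#'
#' Monte-Carlo posterior means that avoid the Normal/Inverse-Gamma prior
#' assumption: for each batch and feature, the posterior
#' \eqn{(\gamma^*, \delta^{2*})} is the likelihood-weighted average of the
#' other features' \eqn{(\hat\gamma_{ig'}, \hat\delta^2_{ig'})} pairs (batch
#' variances Bessel-adjusted to the `n-1` convention as candidates), with
#' weights the Normal likelihood of the feature's standardized batch data at
#' each candidate pair, leave-one-out. Weights are accumulated in log space
#' with max subtraction, so extreme standardized values do not underflow.
#'
#' @inheritParams eb_posterior_parametric
#' @return A `"combat_posterior"` object (all batches flagged converged).
#' @export
eb_posterior_nonparametric <- function(Z, batch, est) {
  Z <- as.matrix(Z)
  G <- ncol(Z)
  if (G < 2L) {
    abort("Non-parametric shrinkage needs at least 2 features.",
          class = "tlcombat_error_input")
  }
  bf <- factor(as.character(batch), levels = est$batch_levels)
  B <- length(est$batch_levels)
  gamma_star <- est$gamma_hat
  delta2_star <- est$delta2_hat

  for (i in seq_len(B)) {
    b <- est$batch_levels[i]
    Zi <- Z[bf == b, , drop = FALSE]
    n_i <- nrow(Zi)
    S1 <- colSums(Zi)
    S2 <- colSums(Zi^2)
    cand_g <- est$gamma_hat[i, ]
    cand_d <- est$delta2_hat[i, ] * n_i / (n_i - 1)
    valid <- is.finite(cand_d) & cand_d > 0

    # log-likelihood of feature g's batch data at candidate (g', d'):
    # -n/2 log(2 pi d') - (S2_g - 2 c_g' S1_g + n c_g'^2) / (2 d')
    const <- ifelse(valid,
                    -n_i / 2 * log(2 * pi * cand_d) - n_i * cand_g^2 / (2 * cand_d),
                    -Inf)
    L <- matrix(const, G, G, byrow = TRUE) +
      outer(S2, ifelse(valid, -1 / (2 * cand_d), 0)) +
      outer(S1, ifelse(valid, cand_g / cand_d, 0))
    diag(L) <- -Inf

    row_max <- apply(L, 1L, max)
    no_candidate <- !is.finite(row_max)
    W <- exp(L - row_max)
    W[no_candidate, ] <- 0
    wsum <- rowSums(W)
    g_post <- as.numeric(W %*% cand_g) / wsum
    d_post <- as.numeric(W %*% cand_d) / wsum

    if (any(no_candidate)) {
      warn(
        paste0("Batch '", b, "': no usable leave-one-out candidates for ",
               sum(no_candidate), " feature(s); kept their raw estimates."),
        class = "tlcombat_warning_nonparametric_fallback"
      )
      g_post[no_candidate] <- cand_g[no_candidate]
      d_post[no_candidate] <- est$delta2_hat[i, no_candidate]
    }
    gamma_star[i, ] <- g_post
    delta2_star[i, ] <- d_post
  }

  structure(
    list(
      gamma_star = gamma_star,
      delta2_star = delta2_star,
      converged = setNames(rep(TRUE, B), est$batch_levels),
      iterations = setNames(integer(B), est$batch_levels),
      batch_levels = est$batch_levels
    ),
    class = "combat_posterior"
  )
}

#' Remove batch effects and restore the pooled scale
#'
#' The standard (grand-mean) adjustment: \eqn{Y^*_{ijg} =
#' (\hat\sigma_g/\hat\delta^*_{ig})(Z_{ijg} - \hat\gamma^*_{ig}) +
#' \hat\alpha_g + X_j\hat\beta_g}. Every sample is mapped to the pooled
#' location and scale of the fitted data.
#'
#' @param Z Standardized matrix.
#' @param post A `"combat_posterior"` object.
#' @param globals A `"combat_globals"` object.
#' @param design Covariate design matrix row-aligned with `Z`.
#' @param batch Per-sample batch labels.
#' @return The adjusted matrix, same shape and dimnames as `Z`.
#' @export
adjust_standard <- function(Z, post, globals, design = NULL, batch = NULL) {
  adjust_to_target(Z, post, globals, design, batch,
                   target_mean = globals$alpha, target_sd = globals$sigma)
}

#' Remove batch effects and rescale to a reference batch
#'
#' The reference-batch adjustment: \eqn{Y^*_{ijg} =
#' (\hat\sigma_{rg}/\hat\delta^*_{ig})(Z_{ijg} - \hat\gamma^*_{ig}) +
#' \hat\alpha_{rg} + X_j\hat\beta_g}, where \eqn{\hat\alpha_{rg}} and
#' \eqn{\hat\sigma_{rg}} are the reference batch's per-feature mean and
#' standard deviation. All samples land on the reference batch's location
#' and scale, which preserves the physical meaning of features such as
#' volumes or uptake values.
#'
#' @inheritParams adjust_standard
#' @param reference_batch The batch id whose moments are the rescaling
#'   target; must be one of the fitted batches.
#' @export
adjust_mcombat <- function(Z, post, globals, design = NULL, batch = NULL,
                           reference_batch) {
  if (!reference_batch %in% globals$batch_levels) {
    abort(
      paste0("Unknown reference batch '", reference_batch, "'. Fitted batches: ",
             paste(globals$batch_levels, collapse = ", ")),
      class = "tlcombat_error_unknown_batch"
    )
  }
  adjust_to_target(
    Z, post, globals, design, batch,
    target_mean = globals$per_batch_alpha[reference_batch, ],
    target_sd = globals$per_batch_sigma[reference_batch, ]
  )
}

# Shared adjustment kernel: undo the per-batch location/scale effect on the
# standardized scale, then map onto the requested target moments.
adjust_to_target <- function(Z, post, globals, design, batch,
                             target_mean, target_sd) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (is.null(design)) design <- matrix(numeric(0), nrow = n, ncol = 0L)
  bf <- factor(as.character(batch), levels = post$batch_levels)
  if (anyNA(bf)) {
    unknown <- setdiff(unique(as.character(batch)), post$batch_levels)
    abort(
      paste0("Batch label(s) not in the model registry: ",
             paste(unknown, collapse = ", ")),
      class = "tlcombat_error_unknown_batch"
    )
  }
  idx <- as.integer(bf)
  centred <- Z - post$gamma_star[idx, , drop = FALSE]
  scaled <- centred / sqrt(post$delta2_star[idx, , drop = FALSE])
  out <- sweep(scaled, 2L, target_sd, "*")
  out <- sweep(out, 2L, target_mean, "+")
  out <- out + design %*% globals$beta
  dimnames(out) <- dimnames(Z)
  out
}
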