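# Synthetic multi-center feature tables with known ground-truth batch
# effects, for validating harmonization end to end.

draw_from_spec <- function(spec, G, what, check_moments = TRUE) {
  dist <- spec$dist %||% abort(
    paste0("Prior spec for ", what, " needs a `dist` element."),
    class = "tlcombat_error_config"
  )
  switch(
    dist,
    normal = rnorm(G, spec$mean, spec$sd),
    uniform = runif(G, spec$min, spec$max),
    invgamma = {
      if (check_moments && (!is.numeric(spec$shape) || spec$shape <= 2)) {
        abort(
          paste0("Inverse-gamma prior for ", what,
                 " needs shape > 2 for finite first two moments."),
          class = "tlcombat_error_config"
        )
      }
      1 / rgamma(G, shape = spec$shape, rate = spec$scale)
    },
    uniform_sd = runif(G, spec$min, spec$max)^2,
    fixed = {
      v <- spec$value
      if (length(v) == 1L) rep(v, G) else {
        stopifnot(length(v) == G)
        as.numeric(v)
      }
    },
    abort(paste0("Unknown prior distribution '", dist, "' for ", what, "."),
          class = "tlcombat_error_config")
  )
}

per_batch_specs <- function(spec, batch_names) {
  if (!is.null(spec$dist)) {
    rep(list(spec), length(batch_names))
  } else {
    if (length(spec) != length(batch_names)) {
      abort("Per-batch prior list must have one spec per batch.",
            class = "tlcombat_error_config")
    }
    spec
  }
}

#' Simulate a multi-center feature table with known batch effects
#'
#' Generates samples-by-features data from the generative model behind the
#' harmonization method: per batch \eqn{i} and feature \eqn{g}, an additive
#' effect \eqn{\gamma_{ig}} and a multiplicative effect
#' \eqn{\delta^2_{ig}} are drawn on the standardized scale (by default from
#' the conjugate Normal / Inverse-Gamma priors) and mapped through the
#' feature's base scale:
#' \deqn{Y_{ijg} = \alpha_g + X_j\beta_g + \sigma_g(\gamma_{ig} +
#'   \delta_{ig}\varepsilon_{ijg}), \qquad \varepsilon \sim N(0, 1).}
#' An optional binary outcome is drawn from a logistic link on the
#' biological (batch-independent) variation of a subset of informative
#' features, so harmonization can remove batch effects without destroying
#' outcome signal. The default batch layout (117/44/28) and event fraction
#' (0.34) emulate a three-center clinical radiomics cohort.
#'
#' @param n_features Number of features `G`.
#' @param batch_sizes Named integer vector of per-batch sample counts.
#' @param gamma_spec Prior for the additive effects: a single spec list
#'   applied to every batch, or a list with one spec per batch. Specs:
#'   `list(dist = "normal", mean, sd)`, `list(dist = "uniform", min, max)`,
#'   or `list(dist = "fixed", value)` (scalar or length-`G`).
#' @param delta2_spec Prior for the multiplicative effects:
#'   `list(dist = "invgamma", shape, scale)` (shape > 2),
#'   `list(dist = "uniform_sd", min, max)` (uniform on the scale factor
#'   \eqn{\delta}, then squared), or `list(dist = "fixed", value)`.
#' @param alpha,sigma Optional length-`G` base means / scales; defaults are
#'   drawn as \eqn{\alpha_g \sim N(10, 2)} and
#'   \eqn{\sigma_g \sim U(0.5, 2)}.
#' @param n_covariates Number of standard-Normal numeric covariates.
#' @param beta_sd Standard deviation of the covariate effect sizes.
#' @param outcome If `TRUE`, draw a binary outcome column.
#' @param event_fraction Target outcome prevalence (default 0.34).
#' @param n_informative Number of outcome-informative features.
#' @param outcome_effect Scale of the logistic linear predictor.
#' @param standardized_scale If `TRUE` (default) batch effects act on the
#'   standardized scale and are mapped through \eqn{\sigma_g}; if `FALSE`
#'   they are injected on the raw feature scale.
#' @param check_moments If `TRUE`, reject inverse-gamma priors with
#'   shape <= 2.
#' @param seed Mandatory RNG seed; the dataset is reproducible from
#'   `(spec, seed)` and the caller's RNG stream is untouched.
#' @return A list of class `"combat_sim"`: `data` (tibble with `sample_id`,
#'   `batch`, covariates, optional `outcome`, features `feat_*`) and
#'   `truth` (drawn `alpha`, `sigma`, `beta`, `gamma`, `delta2`,
#'   informative-feature set and outcome link), plus the seed.
#' @examples
#' sim <- simulate_batch_data(n_features = 5,
#'                            batch_sizes = c(A = 10, B = 12), seed = 1)
#' head(sim$data)
#' sim$truth$gamma
#' @export
simulate_batch_data <- function(n_features = 100,
                                batch_sizes = c(Brest = 117, Nantes = 44,
                                                Montreal = 28),
                                gamma_spec = list(dist = "normal",
                                                  mean = 0, sd = 1),
                                delta2_spec = list(dist = "invgamma",
                                                   shape = 4, scale = 3),
                                alpha = NULL, sigma = NULL,
                                n_covariates = 0, beta_sd = 0.5,
                                outcome = TRUE, event_fraction = 0.34,
                                n_informative = 10, outcome_effect = 1,
                                standardized_scale = TRUE,
                                check_moments = TRUE, seed) {
  if (missing(seed)) {
    abort("`seed` is mandatory for the synthetic generator.",
          class = "tlcombat_error_config")
  }
  G <- as.integer(n_features)
  if (is.null(names(batch_sizes))) {
    names(batch_sizes) <- LETTERS[seq_along(batch_sizes)]
  }
  if (any(batch_sizes < 2L)) {
    abort("Every batch needs at least 2 samples.",
          class = "tlcombat_error_config")
  }
  if (outcome && (event_fraction <= 0 || event_fraction >= 1)) {
    abort("`event_fraction` must be in (0, 1).",
          class = "tlcombat_error_config")
  }
  batch_names <- names(batch_sizes)
  B <- length(batch_sizes)
  n <- sum(batch_sizes)
  feature_names <- sprintf("feat_%03d", seq_len(G))
  gamma_specs <- per_batch_specs(gamma_spec, batch_names)
  delta2_specs <- per_batch_specs(delta2_spec, batch_names)

  with_preserved_seed(seed, {
    alpha_g <- if (is.null(alpha)) rnorm(G, 10, 2) else {
      stopifnot(length(alpha) == G)
      as.numeric(alpha)
    }
    sigma_g <- if (is.null(sigma)) runif(G, 0.5, 2) else {
      stopifnot(length(sigma) == G, all(sigma > 0))
      as.numeric(sigma)
    }
    names(alpha_g) <- names(sigma_g) <- feature_names

    gamma <- t(vapply(gamma_specs, draw_from_spec, numeric(G),
                      G = G, what = "gamma", check_moments = check_moments))
    delta2 <- t(vapply(delta2_specs, draw_from_spec, numeric(G),
                       G = G, what = "delta2", check_moments = check_moments))
    dimnames(gamma) <- dimnames(delta2) <- list(batch_names, feature_names)
    if (any(delta2 <= 0)) {
      abort("Drawn multiplicative effects must be strictly positive.",
            class = "tlcombat_error_config")
    }

    batch <- rep(batch_names, times = batch_sizes)
    idx <- rep(seq_len(B), times = batch_sizes)

    X <- NULL
    beta <- matrix(numeric(0), nrow = 0L, ncol = G,
                   dimnames = list(NULL, feature_names))
    cov_effect <- matrix(0, n, G)
    if (n_covariates > 0L) {
      X <- matrix(rnorm(n * n_covariates), n, n_covariates,
                  dimnames = list(NULL, sprintf("cov_%d", seq_len(n_covariates))))
      beta <- matrix(rnorm(n_covariates * G, 0, beta_sd), n_covariates, G,
                     dimnames = list(colnames(X), feature_names))
      cov_effect <- X %*% beta
    }

    eps <- matrix(rnorm(n * G), n, G)
    shift <- gamma[idx, , drop = FALSE]
    noise <- sqrt(delta2[idx, , drop = FALSE]) * eps
    Y <- if (standardized_scale) {
      sweep(shift + noise, 2L, sigma_g, "*")
    } else {
      shift + noise
    }
    Y <- sweep(Y, 2L, alpha_g, "+") + cov_effect
    colnames(Y) <- feature_names

    out <- tibble(
      sample_id = sprintf("s%04d", seq_len(n)),
      batch = batch
    )
    if (!is.null(X)) out <- dplyr::bind_cols(out, as_tibble(X))

    outcome_truth <- NULL
    if (outcome) {
      k <- min(n_informative, G)
      informative <- feature_names[seq_len(k)]
      w <- rep(outcome_effect / sqrt(k), k)
      s <- eps[, seq_len(k), drop = FALSE] %*% w
      b0 <- uniroot(function(b) mean(plogis(b + s)) - event_fraction,
                    c(-30, 30))$root
      y <- rbinom(n, 1L, plogis(b0 + s))
      out$outcome <- as.integer(y)
      outcome_truth <- list(informative_features = informative,
                            weights = setNames(w, informative),
                            intercept = b0)
    }
    out <- dplyr::bind_cols(out, as_tibble(Y))

    structure(
      list(
        data = out,
        truth = c(
          list(alpha = alpha_g, sigma = sigma_g, beta = beta,
               gamma = gamma, delta2 = delta2),
          outcome_truth
        ),
        seed = as.integer(seed)
      ),
      class = "combat_sim"
    )
  })
}

#' Split a sample table into training and held-out sets
#'
#' Stratified random splitting for hold-out experiments. With
#' `holdout_batch` set, every sample of that batch goes to the test set
#' (the "new center" scenario) and the remaining samples are split by
#' `test_fraction`; otherwise the whole table is split. With `stratify_by`
#' set (typically the outcome column), the split preserves that column's
#' class fractions to within one sample per stratum.
#'
#' @param data A data frame of samples.
#' @param test_fraction Fraction of (remaining) samples assigned to test;
#'   must be in (0, 1).
#' @param holdout_batch Optional batch id whose samples all go to test.
#' @param stratify_by Optional column name to stratify on.
#' @param batch Name of the batch column (used with `holdout_batch`).
#' @param seed Mandatory RNG seed.
#' @return A list with tibbles `train` and `test` (disjoint, covering
#'   `data`).
#' @examples
#' sim <- simulate_batch_data(n_features = 4,
#'                            batch_sizes = c(A = 20, B = 20), seed = 1)
#' parts <- split_holdout(sim$data, 0.3, stratify_by = "outcome", seed = 2)
#' nrow(parts$test)
#' @export
split_holdout <- function(data, test_fraction, holdout_batch = NULL,
                          stratify_by = NULL, batch = "batch", seed) {
  if (missing(seed)) {
    abort("`seed` is mandatory for splitting.", class = "tlcombat_error_config")
  }
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1).", class = "tlcombat_error_config")
  }
  data <- as_tibble(data)
  n <- nrow(data)
  forced <- integer(0)
  if (!is.null(holdout_batch)) {
    if (!holdout_batch %in% data[[batch]]) {
      abort(paste0("Holdout batch '", holdout_batch, "' not present."),
            class = "tlcombat_error_unknown_batch")
    }
    forced <- which(data[[batch]] == holdout_batch)
  }
  pool <- setdiff(seq_len(n), forced)

  test_idx <- with_preserved_seed(seed, {
    if (is.null(stratify_by)) {
      sample(pool, round(test_fraction * length(pool)))
    } else {
      strata <- split(pool, as.character(data[[stratify_by]])[pool])
      unlist(lapply(strata, function(rows) {
        sample(rows, round(test_fraction * length(rows)))
      }), use.names = FALSE)
    }
  })
  test_idx <- sort(c(forced, test_idx))
  list(
    train = data[setdiff(seq_len(n), test_idx), , drop = FALSE],
    test = data[test_idx, , drop = FALSE]
  )
}
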