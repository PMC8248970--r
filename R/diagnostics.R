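# The statistical battery used to judge harmonization: per-feature ANOVA
# across batch labels, two-sample KS, coefficient-of-variation summaries,
# top-2 PCA, and Welch's t-test.

#' Per-feature one-way ANOVA across batch labels
#'
#' Tests, feature by feature, whether the feature's mean differs across
#' batches (classic fixed-effects one-way ANOVA). The share of features
#' significant at `alpha` summarizes how much batch-related signal remains:
#' near 1 before harmonization of strongly batch-shifted data, near the
#' nominal `alpha` (or below) after.
#'
#' @param data A data frame of samples.
#' @param batch Name of the batch column.
#' @param features Feature column names; defaults to all remaining numeric
#'   columns (minus `id`/`exclude`).
#' @param alpha Significance level for the summary fraction.
#' @param exclude Columns to ignore when auto-detecting features (e.g. an
#'   outcome column).
#' @param id Name of the sample identifier column, ignored if absent.
#' @return A tibble with one row per feature: `feature`, `statistic`
#'   (the F value), `p.value`, `significant`, `degenerate` (flagged when
#'   every batch has zero within-group variance, where the p-value is the
#'   0/1 limit). The fraction significant is attached as attribute
#'   `fraction_significant`; see [fraction_significant()].
#' @export
batch_anova <- function(data, batch = "batch", features = NULL,
                        alpha = 0.01, exclude = NULL, id = "sample_id") {
  data <- as_tibble(data)
  labels <- factor(data[[batch]])
  if (nlevels(labels) < 2L) {
    abort("ANOVA needs at least 2 batches.", class = "tlcombat_error_input")
  }
  check_batch_sizes_quietly(labels)
  if (is.null(features)) {
    reserved <- c(batch, exclude, intersect(id, names(data)))
    candidates <- setdiff(names(data), reserved)
    features <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  }

  res <- purrr::map(features, function(f) {
    x <- data[[f]]
    wvar <- tapply(x, labels, var)
    if (all(wvar == 0)) {
      means <- tapply(x, labels, mean)
      same <- max(means) - min(means) == 0
      return(tibble(feature = f,
                    statistic = if (same) 0 else Inf,
                    p.value = if (same) 1 else 0,
                    degenerate = TRUE))
    }
    ft <- oneway.test(x ~ labels, var.equal = TRUE)
    tibble(feature = f, statistic = unname(ft$statistic),
           p.value = unname(ft$p.value), degenerate = FALSE)
  })
  out <- dplyr::bind_rows(res)
  out$significant <- out$p.value < alpha
  attr(out, "fraction_significant") <- mean(out$significant)
  attr(out, "alpha") <- alpha
  out
}

# size-2 floor without re-emitting the advisory small-batch warning
check_batch_sizes_quietly <- function(labels) {
  counts <- table(labels)
  if (any(counts < 2L)) {
    abort(
      paste0("Batch(es) with fewer than 2 samples: ",
             paste(names(counts)[counts < 2L], collapse = ", ")),
      class = "tlcombat_error_batch_size"
    )
  }
  invisible(NULL)
}

#' Fraction of features significant in a diagnostics table
#'
#' @param x A tibble from [batch_anova()] (or any table with a `p.value`
#'   column).
#' @param alpha Significance level; defaults to the one used by
#'   [batch_anova()].
#' @return A single number in `[0, 1]`.
#' @export
fraction_significant <- function(x, alpha = attr(x, "alpha") %||% 0.01) {
  mean(x$p.value < alpha)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Classical two-sample KS statistic with the asymptotic p-value, used to
#' compare the distribution of a feature (or of pooled harmonized values)
#' between two sample sets, e.g. jointly-harmonized vs transfer-harmonized
#' versions of the same samples.
#'
#' @param a,b Numeric sample vectors (non-empty).
#' @return A one-row tibble with `statistic` (the KS D) and `p.value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both samples must be non-empty.", class = "tlcombat_error_input")
  }
  if (min(length(a), length(b)) < 5L) {
    warn("Sample size below 5; the asymptotic KS p-value is unreliable.",
         class = "tlcombat_warning_small_sample")
  }
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' Coefficient-of-variation summary of a feature table
#'
#' Per-feature percent coefficient of variation,
#' \eqn{100 \cdot SD_g / |mean_g|}, plus its sum over features as a single
#' dispersion summary of the table. Features with zero mean or zero
#' standard deviation are excluded and listed in the `excluded` attribute.
#'
#' @param data A data frame of samples.
#' @param features Feature column names; defaults to all numeric columns
#'   minus `exclude`/`id`.
#' @param exclude,id Columns ignored during auto-detection.
#' @return A tibble (`feature`, `mean`, `sd`, `cov`) with attributes
#'   `aggregate` (sum of the `cov` column) and `excluded`.
#' @export
cov_summary <- function(data, features = NULL, exclude = NULL,
                        id = "sample_id") {
  data <- as_tibble(data)
  if (is.null(features)) {
    reserved <- c(exclude, intersect(c(id, "batch"), names(data)))
    candidates <- setdiff(names(data), reserved)
    features <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  }
  mu <- vapply(data[features], mean, numeric(1))
  s <- vapply(data[features], sd, numeric(1))
  keep <- mu != 0 & s > 0
  if (!any(keep)) {
    abort("No feature with non-zero mean and variance; COV undefined.",
          class = "tlcombat_error_input")
  }
  out <- tibble(feature = features[keep], mean = unname(mu[keep]),
                sd = unname(s[keep]),
                cov = unname(100 * s[keep] / abs(mu[keep])))
  attr(out, "aggregate") <- sum(out$cov)
  attr(out, "excluded") <- features[!keep]
  if (any(!keep)) {
    inform(paste0("Excluded from COV (zero mean or constant): ",
                  paste(features[!keep], collapse = ", ")))
  }
  out
}

#' Top-2 principal components of a feature table
#'
#' Correlation PCA (features centred and unit-scaled) of the samples,
#' returning the first two component scores and their explained-variance
#' fractions. Batch-shifted data typically separates by batch along PC1;
#' harmonized data should overlap. The sign convention fixes each
#' component so its largest-magnitude loading is positive.
#'
#' @inheritParams cov_summary
#' @param batch Name of a batch column to carry into the scores table
#'   (ignored if absent).
#' @return A list of class `"combat_pca"`: `scores` (tibble with ids,
#'   batch if present, `PC1`, `PC2`), `var_explained` (length-2 fractions),
#'   and `loadings`.
#' @export
pca_top2 <- function(data, features = NULL, exclude = NULL,
                     id = "sample_id", batch = "batch") {
  data <- as_tibble(data)
  if (is.null(features)) {
    reserved <- c(exclude, intersect(c(id, batch), names(data)))
    candidates <- setdiff(names(data), reserved)
    features <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  }
  if (nrow(data) < 3L) {
    abort("PCA needs at least 3 samples.", class = "tlcombat_error_input")
  }
  X <- as.matrix(data[features])
  nondeg <- apply(X, 2L, function(x) sd(x) > 0)
  if (sum(nondeg) < 2L) {
    abort("PCA needs at least 2 non-degenerate features.",
          class = "tlcombat_error_input")
  }
  X <- X[, nondeg, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)

  tab <- tibble(.rows = nrow(data))
  if (id %in% names(data)) tab[[id]] <- data[[id]]
  if (batch %in% names(data)) tab[[batch]] <- data[[batch]]
  tab$PC1 <- scores[, 1L]
  tab$PC2 <- if (k > 1L) scores[, 2L] else NA_real_
  structure(
    list(scores = tab,
         var_explained = ve[seq_len(2L)],
         loadings = loadings),
    class = "combat_pca"
  )
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t-test with Welch-Satterthwaite degrees of freedom, used to
#' compare paired sets of performance metrics or feature summaries. When
#' both samples are constant the test degenerates: p = 1 if the means are
#' equal, p = 0 otherwise.
#'
#' @param a,b Numeric sample vectors with at least 2 values each.
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("Both samples need at least 2 values.", class = "tlcombat_error_input")
  }
  if (var(a) == 0 && var(b) == 0) {
    same <- mean(a) == mean(b)
    return(tibble(statistic = if (same) 0 else Inf,
                  df = NA_real_, p.value = if (same) 1 else 0))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = unname(tt$p.value))
}

#' Full harmonization diagnostics report
#'
#' Bundles the battery used to verify harmonization of a feature table:
#' per-feature ANOVA across batches with its significant fraction, the COV
#' summary, and the top-2 PCA.
#'
#' @inheritParams batch_anova
#' @return A list of class `"combat_diagnostics"` with elements `anova`,
#'   `fraction_significant`, `cov`, `cov_aggregate`, `pca`, `alpha`.
#'   Supports [generics::tidy()], [generics::glance()], and
#'   [ggplot2::autoplot()].
#' @examples
#' sim <- simulate_batch_data(n_features = 10,
#'                            batch_sizes = c(A = 20, B = 20), seed = 1)
#' diag <- harmonization_diagnostics(sim$data, exclude = "outcome")
#' glance(diag)
#' @export
harmonization_diagnostics <- function(data, batch = "batch", features = NULL,
                                      alpha = 0.01, exclude = NULL,
                                      id = "sample_id") {
  an <- batch_anova(data, batch = batch, features = features, alpha = alpha,
                    exclude = exclude, id = id)
  cv <- suppressMessages(
    cov_summary(data, features = features, exclude = c(exclude, batch), id = id)
  )
  pc <- pca_top2(data, features = features, exclude = exclude,
                 id = id, batch = batch)
  structure(
    list(
      anova = an,
      fraction_significant = attr(an, "fraction_significant"),
      cov = cv,
      cov_aggregate = attr(cv, "aggregate"),
      pca = pc,
      alpha = alpha
    ),
    class = "combat_diagnostics"
  )
}

#' @export
print.combat_diagnostics <- function(x, ...) {
  cat("Harmonization diagnostics\n")
  cat("  features tested: ", nrow(x$anova), "\n", sep = "")
  cat("  ANOVA significant fraction (alpha = ", x$alpha, "): ",
      format(x$fraction_significant, digits = 3), "\n", sep = "")
  cat("  aggregate COV: ", format(x$cov_aggregate, digits = 5), "\n", sep = "")
  cat("  PC1/PC2 variance explained: ",
      paste(format(x$pca$var_explained, digits = 3), collapse = " / "),
      "\n", sep = "")
  invisible(x)
}
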