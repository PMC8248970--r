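# Shared fixtures and independent oracles. Everything is generated in code
# at test time; no stored data.

feat_cols <- function(data) grep("^feat_", names(data), value = TRUE)

feat_mat <- function(data) as.matrix(data[feat_cols(data)])

# Conjugate-prior generative setting with center-specific prior means
# (the estimable part of the additive effects needs distinct centers).
priors_sim <- function(n_features, sizes, seed, tau = 0.3, ...) {
  means <- c(-1, 0.5, 1.5)[seq_along(sizes)]
  simulate_batch_data(
    n_features = n_features, batch_sizes = sizes,
    gamma_spec = lapply(means, function(m) list(dist = "normal", mean = m,
                                                sd = tau)),
    delta2_spec = list(dist = "invgamma", shape = 4, scale = 3),
    outcome = FALSE, seed = seed, ...
  )
}

# Small 3-batch dataset with clear batch effects, no covariates.
shifted_sim <- function(n_features = 25, sizes = c(A = 40, B = 30, C = 30),
                        seed = 42, ...) {
  simulate_batch_data(
    n_features = n_features, batch_sizes = sizes,
    gamma_spec = list(dist = "uniform", min = -2, max = 2),
    delta2_spec = list(dist = "uniform_sd", min = 0.5, max = 2),
    outcome = FALSE, seed = seed, ...
  )
}

# Independent closed-form oracle for shrinkage-off harmonization without
# covariates: per-batch location-scale alignment onto the pooled moments,
# written with plain loops (no package internals).
oracle_location_scale <- function(Y, batch) {
  bf <- factor(batch, levels = unique(batch))
  n <- nrow(Y)
  B <- nlevels(bf)
  out <- Y
  for (g in seq_len(ncol(Y))) {
    y <- Y[, g]
    bm <- tapply(y, bf, mean)
    alpha <- sum(bm * as.integer(table(bf))) / n
    rss <- sum((y - bm[as.integer(bf)])^2)
    sigma <- sqrt(rss / n) # population residual SD
    for (b in levels(bf)) {
      rows <- bf == b
      m <- mean(y[rows])
      s_pop <- sqrt(mean((y[rows] - m)^2))
      out[rows, g] <- (y[rows] - m) / s_pop * sigma + alpha
    }
  }
  out
}

# Brute-force metric oracle straight from the confusion-matrix definitions.
oracle_metrics <- function(tp, fn, tn, fp) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(bacc = (sens + spec) / 2, mcc = if (den == 0) 0 else num / den)
}

# Labels/scores realizing a given confusion matrix at threshold 0.5.
confusion_data <- function(tp, fn, tn, fp) {
  list(
    y = c(rep(1, tp), rep(1, fn), rep(0, tn), rep(0, fp)),
    s = c(rep(0.9, tp), rep(0.1, fn), rep(0.1, tn), rep(0.9, fp))
  )
}
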