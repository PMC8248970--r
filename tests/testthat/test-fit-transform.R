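test_that("single-batch data with shrinkage off passes through unchanged", {
  set.seed(81)
  n <- 30
  df <- tibble::tibble(
    sample_id = paste0("s", 1:n), batch = "A",
    feat_1 = rnorm(n, 5, 2), feat_2 = rnorm(n, 0, 1)
  )
  fit <- combat_fit(df, eb = "none")
  expect_lt(max(abs(feat_mat(fit$harmonized) - feat_mat(df))), 1e-8)
})

test_that("harmonization removes injected batch differences", {
  sim <- shifted_sim(n_features = 60, sizes = c(A = 60, B = 50, C = 40),
                     seed = 83)
  pre <- batch_anova(sim$data, alpha = 0.01)
  expect_gte(fraction_significant(pre), 0.9)
  fit <- combat_fit(sim$data)
  post <- batch_anova(fit$harmonized, alpha = 0.01)
  expect_lte(fraction_significant(post), 0.02)
})

test_that("fitting is deterministic: identical inputs give bitwise-identical outputs", {
  sim <- shifted_sim(seed = 85)
  f1 <- combat_fit(sim$data)
  f2 <- combat_fit(sim$data)
  expect_identical(f1$harmonized, f2$harmonized)
  expect_identical(f1$gamma_star, f2$gamma_star)
})

test_that("outputs conserve shape, identifiers, and finiteness across variants and modes", {
  sim <- shifted_sim(n_features = 15, sizes = c(A = 25, B = 20, C = 20),
                     seed = 87)
  for (v in c("combat", "m-combat", "b-combat", "bm-combat")) {
    for (e in c("parametric", "nonparametric")) {
      fit <- combat_fit(
        sim$data, variant = v, eb = e,
        reference_batch = if (v %in% c("m-combat", "bm-combat")) "A",
        seed = if (v %in% c("b-combat", "bm-combat")) 9,
        bootstrap_reps = 20
      )
      h <- fit$harmonized
      expect_identical(dim(h), dim(sim$data))
      expect_identical(h$sample_id, sim$data$sample_id)
      expect_identical(h$batch, sim$data$batch)
      expect_identical(names(h), names(sim$data))
      expect_true(all(is.finite(feat_mat(h))))
    }
  }
})

test_that("between-batch location and scale differences shrink after harmonization", {
  sim <- shifted_sim(n_features = 30, sizes = c(A = 220, B = 200, C = 210),
                     seed = 89)
  Y <- feat_mat(sim$data)
  bf <- factor(sim$data$batch)
  mean_spread <- function(M) {
    max(vapply(seq_len(ncol(M)), function(g) {
      bm <- tapply(M[, g], bf, mean)
      max(bm) - min(bm)
    }, numeric(1)))
  }
  pre_spread <- mean_spread(Y)
  for (v in c("combat", "m-combat", "b-combat", "bm-combat")) {
    fit <- combat_fit(
      sim$data, variant = v,
      reference_batch = if (v %in% c("m-combat", "bm-combat")) "A",
      seed = if (v %in% c("b-combat", "bm-combat")) 13,
      bootstrap_reps = 30
    )
    H <- feat_mat(fit$harmonized)
    expect_lt(mean_spread(H), 0.1 * pre_spread)
    # per-batch variances agree across batches after harmonization
    for (g in seq_len(ncol(H))) {
      v_b <- tapply(H[, g], bf, var)
      expect_lt(max(v_b) / min(v_b), 1.2 / 0.8)
    }
  }
})

test_that("posterior additive effects track the generating truth", {
  sim <- priors_sim(n_features = 200, sizes = c(A = 200, B = 200, C = 200),
                    seed = 91)
  fit <- combat_fit(sim$data)
  expect_gt(cor(as.vector(fit$gamma_star), as.vector(sim$truth$gamma)), 0.95)
})

test_that("harmonization under the null leaves values nearly unchanged", {
  sim <- simulate_batch_data(
    n_features = 40, batch_sizes = c(A = 120, B = 110, C = 100),
    gamma_spec = list(dist = "fixed", value = 0),
    delta2_spec = list(dist = "fixed", value = 1),
    outcome = FALSE, seed = 93
  )
  fit <- combat_fit(sim$data)
  delta <- abs(feat_mat(fit$harmonized) - feat_mat(sim$data))
  rel <- sweep(delta, 2L, sim$truth$sigma, "/")
  expect_lt(mean(rel), 0.1)
})

test_that("reference-batch harmonization preserves positivity of volume-like features", {
  set.seed(95)
  sim <- simulate_batch_data(
    n_features = 20, batch_sizes = c(A = 60, B = 50, C = 40),
    gamma_spec = list(dist = "uniform", min = -0.8, max = 0.8),
    delta2_spec = list(dist = "uniform_sd", min = 0.7, max = 1.4),
    alpha = runif(20, 20, 60), sigma = runif(20, 1, 3),
    outcome = FALSE, seed = 95
  )
  fitm <- combat_fit(sim$data, variant = "m-combat", reference_batch = "A")
  ref_rows <- sim$data$batch == "A"
  expect_true(all(feat_mat(sim$data)[ref_rows, ] > 0))
  expect_true(all(feat_mat(fitm$harmonized)[ref_rows, ] > 0))
})

test_that("configuration contracts are enforced", {
  sim <- shifted_sim(seed = 97)
  expect_error(combat_fit(sim$data, variant = "m-combat"),
               class = "tlcombat_error_config")
  expect_error(combat_fit(sim$data, variant = "m-combat", reference_batch = "Z"),
               class = "tlcombat_error_unknown_batch")
  expect_error(combat_fit(sim$data, variant = "b-combat"),
               class = "tlcombat_error_config")
  expect_error(combat_fit(sim$data, reference_batch = "A"),
               class = "tlcombat_error_config")

  one <- sim$data[c(1, 2, 3, which(sim$data$batch == "B")[1]), ]
  expect_error(combat_fit(one), class = "tlcombat_error_batch_size")
})

test_that("constant features error by default and can be dropped on request", {
  sim <- shifted_sim(n_features = 6, seed = 99)
  d <- sim$data
  d$feat_001 <- 5
  expect_error(combat_fit(d), "feat_001",
               class = "tlcombat_error_constant_feature")
  fit <- suppressMessages(combat_fit(d, drop_constant = TRUE))
  expect_false("feat_001" %in% fit$feature_names)
  expect_equal(length(fit$feature_names), 5L)
})
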