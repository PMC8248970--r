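test_that("model JSON round-trips field for field and through transforms", {
  sim <- shifted_sim(n_features = 8, sizes = c(A = 15, B = 12, C = 10),
                     seed = 111)
  fit <- combat_fit(sim$data, variant = "bm-combat", reference_batch = "B",
                    eb = "parametric", seed = 5, bootstrap_reps = 15)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  keep <- setdiff(names(fit), "harmonized")
  expect_identical(fit[keep], back[keep])
  # persistence transparency: stored and in-memory models transform alike
  expect_identical(combat_apply(fit, sim$data), combat_apply(back, sim$data))
})

test_that("corrupt or incompatible model files fail with explicit errors", {
  sim <- shifted_sim(n_features = 4, sizes = c(A = 10, B = 10), seed = 113)
  fit <- combat_fit(sim$data)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)

  txt <- readLines(path)
  trunc_path <- withr::local_tempfile(fileext = ".json")
  writeLines(head(txt, length(txt) %/% 2), trunc_path)
  expect_error(load_model(trunc_path), class = "tlcombat_error_model_file")

  obj <- jsonlite::read_json(path)
  obj$schema_version <- "99.0"
  v_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, v_path, auto_unbox = TRUE, null = "null")
  expect_error(load_model(v_path), class = "tlcombat_error_model_schema")

  obj2 <- jsonlite::read_json(path)
  # drop batch B's estimator row
  obj2$gamma_star$rownames <- obj2$gamma_star$rownames[1]
  obj2$gamma_star$values <- obj2$gamma_star$values[c(1, 3, 5, 7)]
  obj2$gamma_star$dim <- list(1L, 4L)
  b_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj2, b_path, auto_unbox = TRUE, null = "null")
  expect_error(load_model(b_path), "B", class = "tlcombat_error_model_schema")
})

test_that("transforming the training data reproduces the fit-time output for all variants", {
  sim <- shifted_sim(n_features = 10, sizes = c(A = 20, B = 18, C = 16),
                     seed = 115, n_covariates = 1)
  for (v in c("combat", "m-combat", "b-combat", "bm-combat")) {
    for (e in c("parametric", "nonparametric")) {
      fit <- combat_fit(
        sim$data, covariates = "cov_1", variant = v, eb = e,
        reference_batch = if (v %in% c("m-combat", "bm-combat")) "A",
        seed = if (v %in% c("b-combat", "bm-combat")) 3,
        bootstrap_reps = 10
      )
      again <- combat_apply(fit, sim$data)
      expect_lt(max(abs(feat_mat(again) - feat_mat(fit$harmonized))), 1e-8)
    }
  }
})

test_that("transform contracts: unknown batches and feature mismatches are rejected", {
  sim <- shifted_sim(n_features = 5, sizes = c(A = 12, B = 12), seed = 117)
  fit <- combat_fit(sim$data)

  new_batch <- sim$data
  new_batch$batch[1] <- "Nantes"
  expect_error(combat_apply(fit, new_batch), "Nantes",
               class = "tlcombat_error_unknown_batch")

  missing_feat <- sim$data[setdiff(names(sim$data), "feat_002")]
  expect_error(combat_apply(fit, missing_feat), "feat_002",
               class = "tlcombat_error_features")

  extra <- sim$data
  extra$feat_999 <- rnorm(nrow(extra))
  expect_error(combat_apply(extra_model <- fit, extra), "feat_999",
               class = "tlcombat_error_features")
})

test_that("transforming one sample at a time matches the batched transform", {
  sim <- shifted_sim(n_features = 6, sizes = c(A = 14, B = 14), seed = 119)
  fit <- combat_fit(sim$data)
  whole <- combat_apply(fit, sim$data)
  rows <- c(1, 8, 20)
  for (r in rows) {
    single <- combat_apply(fit, sim$data[r, ])
    expect_equal(single, whole[r, ])
  }
})

test_that("feature column order does not change the result", {
  sim <- shifted_sim(n_features = 7, sizes = c(A = 12, B = 12), seed = 121)
  fit <- combat_fit(sim$data)
  shuffled <- sim$data[c("sample_id", "batch", rev(feat_cols(sim$data)))]
  out <- combat_apply(fit, shuffled)
  ref <- combat_apply(fit, sim$data)
  expect_equal(out[feat_cols(sim$data)], ref[feat_cols(sim$data)])
  expect_identical(names(out), names(shuffled))
})

test_that("new samples from the training batches' generative law transfer cleanly", {
  # fixed per-batch effects so that fresh samples follow the exact law the
  # model was trained on; the new cohort is small relative to the training
  # set, keeping the stored-estimator noise floor below the ANOVA alpha
  G <- 300
  set.seed(123)
  gamma_fix <- lapply(c(-1, 0.3, 1.2), function(m) {
    list(dist = "fixed", value = rnorm(G, m, 0.4))
  })
  delta2_fix <- lapply(1:3, function(i) {
    list(dist = "fixed", value = runif(G, 0.6, 1.6)^2)
  })
  alpha_fix <- rnorm(G, 10, 2)
  sigma_fix <- runif(G, 0.5, 2)
  gen <- function(sizes, seed) {
    simulate_batch_data(
      n_features = G, batch_sizes = sizes,
      gamma_spec = gamma_fix, delta2_spec = delta2_fix,
      alpha = alpha_fix, sigma = sigma_fix,
      outcome = FALSE, seed = seed
    )
  }
  train <- gen(c(A = 300, B = 250, C = 200), seed = 124)
  new <- gen(c(A = 15, B = 15, C = 15), seed = 125)
  new$data$sample_id <- paste0("new_", new$data$sample_id)

  fit_train <- combat_fit(train$data)
  tl <- combat_apply(fit_train, new$data)
  expect_lte(fraction_significant(batch_anova(tl, alpha = 0.01)), 0.02)

  # the same new samples harmonized jointly with all data look the same
  pooled <- dplyr::bind_rows(train$data, new$data)
  fit_all <- combat_fit(pooled)
  joint <- fit_all$harmonized[match(new$data$sample_id,
                                    fit_all$harmonized$sample_id), ]
  ks_p <- vapply(feat_cols(new$data), function(f) {
    ks_two_sample(joint[[f]], tl[[f]])$p.value
  }, numeric(1))
  expect_gte(mean(ks_p > 0.05), 0.95)
})
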