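test_that("per-feature ANOVA detects separation and stays calibrated under the null", {
  set.seed(151)
  n <- 50
  d <- tibble::tibble(
    sample_id = paste0("s", 1:(2 * n)),
    batch = rep(c("A", "B"), each = n),
    feat_sep = c(rnorm(n, 0), rnorm(n, 5)),
    feat_null = rnorm(2 * n)
  )
  res <- batch_anova(d, alpha = 0.01)
  expect_lt(res$p.value[res$feature == "feat_sep"], 1e-10)
  expect_true(all(res$p.value >= 0 & res$p.value <= 1))

  # duplicated batches: F = 0, p = 1
  dup <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    batch = rep(c("A", "B"), each = 3),
    feat_x = rep(c(1, 2, 3), 2)
  )
  r2 <- batch_anova(dup)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p.value, 1)

  # degenerate: zero within-group variance
  deg <- tibble::tibble(
    sample_id = paste0("s", 1:4), batch = c("A", "A", "B", "B"),
    feat_diff = c(1, 1, 2, 2), feat_same = c(3, 3, 3, 3)
  )
  r3 <- batch_anova(deg)
  expect_true(all(r3$degenerate))
  expect_equal(r3$p.value[r3$feature == "feat_diff"], 0)
  expect_equal(r3$p.value[r3$feature == "feat_same"], 1)

  # null calibration at G = 2000
  nullsim <- simulate_batch_data(
    n_features = 2000, batch_sizes = c(A = 30, B = 30, C = 30),
    gamma_spec = list(dist = "fixed", value = 0),
    delta2_spec = list(dist = "fixed", value = 1),
    outcome = FALSE, seed = 153
  )
  frac <- fraction_significant(batch_anova(nullsim$data, alpha = 0.01))
  expect_lt(abs(frac - 0.01), 0.005)
})

test_that("two-sample KS behaves at its extremes and under the null", {
  x <- c(0.1, 0.4, 0.5, 0.9, 0.3, 0.7)
  same <- ks_two_sample(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  a <- runif(100)
  b <- runif(100, 10, 11)
  expect_equal(ks_two_sample(a, b)$statistic, 1)

  set.seed(155)
  rej <- mean(vapply(1:1000, function(i) {
    ks_two_sample(rnorm(500), rnorm(500))$p.value < 0.05
  }, numeric(1)))
  expect_lt(abs(rej - 0.05), 0.02)

  expect_warning(ks_two_sample(rnorm(3), rnorm(10)),
                 class = "tlcombat_warning_small_sample")
})

test_that("COV summary follows its definition and drops undefined features", {
  set.seed(157)
  d <- tibble::tibble(
    sample_id = paste0("s", 1:200),
    a = rnorm(200, 10, 1),
    flat = rep(5, 200)
  )
  suppressMessages(cv <- cov_summary(d))
  expect_equal(cv$cov[cv$feature == "a"],
               100 * sd(d$a) / abs(mean(d$a)))
  expect_lt(abs(cv$cov[cv$feature == "a"] - 10), 2)
  expect_false("flat" %in% cv$feature)
  expect_true("flat" %in% attr(cv, "excluded"))
  expect_equal(attr(cv, "aggregate"), sum(cv$cov))

  # permutation invariance of the aggregate
  suppressMessages(cv_perm <- cov_summary(d[, c("sample_id", "flat", "a")]))
  expect_equal(attr(cv_perm, "aggregate"), attr(cv, "aggregate"))
})

test_that("harmonizing scale-inflated batches reduces the aggregate COV", {
  sim <- shifted_sim(n_features = 40, sizes = c(A = 60, B = 60, C = 60),
                     seed = 159)
  fit <- combat_fit(sim$data)
  pre <- attr(suppressMessages(cov_summary(sim$data)), "aggregate")
  post <- attr(suppressMessages(cov_summary(fit$harmonized)), "aggregate")
  expect_lt(post, pre)
})

test_that("top-2 PCA reports collinear, isotropic, and batch-shifted structure", {
  # exactly collinear data
  t_par <- seq(0, 1, length.out = 20)
  lin <- tibble::tibble(sample_id = paste0("s", 1:20),
                        f1 = t_par, f2 = 2 * t_par, f3 = -t_par)
  p1 <- pca_top2(lin, features = c("f1", "f2", "f3"))
  expect_equal(p1$var_explained[1], 1)
  expect_equal(p1$var_explained[2], 0, tolerance = 1e-12)

  set.seed(161)
  iso <- tibble::tibble(sample_id = paste0("s", 1:2000),
                        f1 = rnorm(2000), f2 = rnorm(2000))
  p2 <- pca_top2(iso, features = c("f1", "f2"))
  expect_lt(abs(p2$var_explained[1] - 0.5), 0.05)
  expect_lt(abs(p2$var_explained[2] - 0.5), 0.05)

  # batch clusters separate along PC1 before harmonization, overlap after
  sim <- shifted_sim(n_features = 30, sizes = c(A = 80, B = 80), seed = 163)
  fit <- combat_fit(sim$data)
  centroid_gap <- function(d) {
    pc <- pca_top2(d)
    m <- tapply(pc$scores$PC1, pc$scores$batch, mean)
    abs(diff(m))
  }
  expect_gt(centroid_gap(sim$data), 5 * centroid_gap(fit$harmonized))

  expect_error(pca_top2(lin, features = c("f1")),
               class = "tlcombat_error_input")
})

test_that("Welch's t-test handles extremes and degenerate input", {
  x <- c(1.2, 0.8, 1.1, 0.9)
  same <- welch_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  set.seed(165)
  big <- welch_t(rnorm(1000, 0), rnorm(1000, 1))
  expect_lt(big$p.value, 1e-10)

  const <- welch_t(c(2, 2, 2), c(2, 2))
  expect_equal(const$p.value, 1)
  expect_equal(welch_t(c(2, 2, 2), c(3, 3))$p.value, 0)

  set.seed(167)
  rej <- mean(vapply(1:1000, function(i) {
    welch_t(rnorm(50), rnorm(50))$p.value < 0.05
  }, numeric(1)))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("the bundled diagnostics report is consistent with its parts", {
  sim <- shifted_sim(n_features = 12, sizes = c(A = 30, B = 30), seed = 169)
  rep <- harmonization_diagnostics(sim$data)
  expect_s3_class(rep, "combat_diagnostics")
  expect_equal(rep$fraction_significant,
               fraction_significant(rep$anova))
  g <- glance(rep)
  expect_equal(g$fraction_significant, rep$fraction_significant)
  td <- tidy(rep)
  expect_true(all(c("p.value", "cov") %in% names(td)))
  plt <- ggplot2::autoplot(rep)
  expect_s3_class(plt, "ggplot")
})
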