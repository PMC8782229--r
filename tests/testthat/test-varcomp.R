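test_that("balanced ANOVA reproduces hand-computed expected-mean-squares arithmetic", {
  # 2 x 2 toy table {(a1,d1)=1, (a1,d2)=2, (a2,d1)=3, (a2,d2)=4}:
  # MS_animal = 4, MS_day = 1, MS_error = 0
  # => s2_animal = 2, s2_day = 0.5, s2_error = 0
  toy <- data.frame(
    animal_id = c("a1", "a1", "a2", "a2"),
    day_index = c(1, 2, 1, 2),
    gas = "O2",
    flux_lph = c(1, 2, 3, 4)
  )
  vc <- fit_anova_balanced(toy, "O2")
  expect_equal(unname(vc$sigma2), c(2, 0.5, 0))
  expect_equal(vc$mu, 2.5)
})

test_that("constant data yields all-zero components and summaries", {
  const <- data.frame(animal_id = rep(c("a1", "a2", "a3"), 4),
                      day_index = rep(1:4, each = 3),
                      gas = "O2", flux_lph = 7)
  vc <- fit_anova_balanced(const, "O2")
  expect_equal(unname(vc$sigma2), c(0, 0, 0))
  expect_equal(vc$H_ani, 0)
  expect_equal(vc$CV, 0)
  expect_equal(vc$repeatability, 0)
})

test_that("unbalanced input to the ANOVA estimator fails with guidance", {
  d <- make_crossed_data(6, 4, c(1, 1, 1), seed = 1)
  expect_error(fit_anova_balanced(d[-1, ], "O2"), "fit_reml")
})

test_that("ANOVA estimator is unbiased for the oxygen variance components", {
  s2 <- unname(oxygen_var_truth)
  reps <- 500L
  est <- vapply(seq_len(reps), function(r) {
    d <- make_crossed_data(48, 17, s2, mu = 0.3582, seed = 3000 + r)
    fit_anova_balanced(d, "O2")$sigma2
  }, numeric(3))
  bias <- abs(rowMeans(est) - s2) / s2
  expect_true(all(bias < 0.05))
})

test_that("restricted log-likelihood routes agree: dense, MME and lme4", {
  d <- make_crossed_data(10, 7, c(1.2, 0.8, 1.5), seed = 21)
  d$animal_f <- factor(d$animal_id)
  d$day_f <- factor(d$day_index)
  X <- matrix(1, nrow(d), 1)
  Za <- model.matrix(~ 0 + animal_f, d)
  Zd <- model.matrix(~ 0 + day_f, d)
  fit <- lme4::lmer(flux_lph ~ 1 + (1 | animal_f) + (1 | day_f), d,
                    REML = TRUE)
  v <- as.data.frame(lme4::VarCorr(fit))
  s2 <- c(v$vcov[v$grp == "animal_f"], v$vcov[v$grp == "day_f"],
          v$vcov[v$grp == "Residual"])
  ll_dense <- reml_loglik(s2, d$flux_lph, X, Za, Zd)
  ll_mme <- pacflux:::.reml_mme_factory(d$flux_lph, X, Za, Zd)(s2)
  expect_equal(ll_dense, ll_mme, tolerance = 1e-10)
  expect_equal(ll_dense, as.numeric(logLik(fit)), tolerance = 1e-8)
})

test_that("REML matches the balanced-ANOVA closed form on interior fits", {
  set.seed(31)
  checked <- 0L
  for (r in 1:40) {
    a <- sample(6:12, 1)
    b <- sample(5:10, 1)
    d <- make_crossed_data(a, b, runif(3, 0.5, 3), seed = 400 + r)
    va <- fit_anova_balanced(d, "O2")
    if (min(va$sigma2) < 0.02 * sum(va$sigma2)) next
    vr <- fit_reml(d, model_spec("O2"), se = FALSE)
    expect_lt(max(abs(vr$sigma2 - va$sigma2) / va$sigma2), 1e-6)
    checked <- checked + 1L
  }
  expect_gte(checked, 20L)
})

test_that("REML recovers the truth on data with 10% of cells missing", {
  s2 <- unname(oxygen_var_truth)
  reps <- 150L
  est <- vapply(seq_len(reps), function(r) {
    d <- make_crossed_data(24, 10, s2, mu = 0.3582, seed = 5000 + r)
    set.seed(6000 + r)
    drop <- sample(nrow(d), round(0.1 * nrow(d)))
    fit_reml(d[-drop, ], model_spec("O2"), se = FALSE)$sigma2
  }, numeric(3))
  bias <- abs(rowMeans(est) - s2) / s2
  expect_true(all(bias < 0.08))
})

test_that("REML drives a truly absent day variance to the boundary", {
  d <- make_crossed_data(48, 17, c(0.006, 0, 0.005), mu = 0.36, seed = 77)
  vc <- fit_reml(d, model_spec("O2"))
  expect_lt(vc$sigma2[["day"]], 0.02 * sum(vc$sigma2))
  expect_lt(abs(vc$sigma2[["animal"]] - 0.006) / 0.006, 0.5)
  expect_lt(abs(vc$sigma2[["error"]] - 0.005) / 0.005, 0.1)
})

test_that("variance shares are non-negative, sum to one, and SEs are positive", {
  fx <- fixture_flux()
  for (g in pac_gases()) {
    vc <- fit_reml(fx, model_spec(g))
    expect_true(all(vc$sigma2 >= 0))
    shares <- vc$sigma2 / sum(vc$sigma2)
    expect_equal(sum(shares), 1)
    expect_equal(vc$H_ani, unname(shares["animal"]))
    expect_true(all(is.na(vc$se) | vc$se > 0))
    expect_false(any(is.na(vc$se[setdiff(names(vc$se),
                                         vc$truncated)])))
  }
})

test_that("derived summaries implement the published ratios", {
  vc <- variance_components(2, 1, 1, mu = 4)
  expect_equal(vc$H_ani, 0.5)
  expect_equal(vc$CV, sqrt(2) / 4)
  expect_equal(vc$repeatability, 2 / 3)
  expect_equal(derive_summaries(vc, "total")$repeatability, 0.5)
  expect_equal(variance_components(0, 1, 1, mu = 4)$repeatability, 0)
  expect_error(variance_components(1, 1, 1, mu = 0), "CV undefined")
})

test_that("windowed repeatability equals the full fit at the full window", {
  fx <- fixture_flux()
  spec <- model_spec("O2", fixed = c("liveweight", "humidity"))
  full <- fit_reml(fx, spec, se = FALSE)$repeatability
  expect_equal(repeatability_by_window(fx, "O2", 17, se = FALSE), full)
  expect_error(repeatability_by_window(fx, "O2", 1), "between 2 and")
  expect_error(repeatability_by_window(fx, "O2", 18), "between 2 and")
})

test_that("windowed repeatability is 1 for noise-free animal differences", {
  d <- make_crossed_data(12, 6, c(1, 0.3, 0), seed = 9)
  expect_gt(repeatability_by_window(d, "O2", 2,
                                    spec = model_spec("O2"), se = FALSE),
            0.999)
})

test_that("nested likelihood-ratio test behaves at the boundary null", {
  fx <- fixture_flux()
  same <- lrt_nested(model_spec("O2"), model_spec("O2"), fx)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(
    lrt_nested(model_spec("O2", random = "animal"), model_spec("O2"), fx),
    "not nested")
  expect_error(
    lrt_nested(model_spec("O2"), model_spec("O2", fixed = "humidity"), fx),
    "share gas and fixed")
  # type-I error under sigma2_day = 0 close to nominal with the
  # 0.5 chi2_0 + 0.5 chi2_1 mixture
  reps <- 150L
  rej <- 0L
  for (b in seq_len(reps)) {
    d <- make_crossed_data(12, 6, c(1, 0, 1), mu = 5, seed = 7000 + b)
    lr <- lrt_nested(model_spec("O2"), model_spec("O2", random = "animal"), d)
    if (lr$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.005)
  expect_lt(rej / reps, 0.11)
})

test_that("nested likelihood-ratio test has power against a real day variance", {
  for (b in 1:20) {
    d <- make_crossed_data(12, 8, c(1, 4, 1), mu = 5, seed = 8000 + b)
    lr <- lrt_nested(model_spec("O2"), model_spec("O2", random = "animal"), d)
    expect_lt(lr$p_value, 0.05)
  }
  # dropping both random effects uses the two-component mixture
  d <- make_crossed_data(12, 8, c(1, 4, 1), mu = 5, seed = 8100)
  lr2 <- lrt_nested(model_spec("O2"), model_spec("O2", random = character(0)), d)
  expect_equal(lr2$df_dropped, 2)
  expect_lt(lr2$p_value, 0.001)
})
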