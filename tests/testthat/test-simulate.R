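test_that("degenerate variances give constant true fluxes at the mean", {
  p <- sim_params(var_animal = c(0, 0, 0), var_day = c(0, 0, 0),
                  var_error = c(0, 0, 0), seed = 3)
  tr <- simulate_trial(p, small_design())
  for (g in pac_gases()) {
    expect_equal(unique(tr$truth$true_flux_lph[tr$truth$gas == g]),
                 unname(p$mean_flux[g]))
  }
})

test_that("trial dimensions and layout invariants hold", {
  tr <- fixture_trial()
  expect_equal(nrow(tr$traces), 48 * 17)
  expect_equal(nrow(tr$truth), 48 * 17 * 3)
  # every animal exactly once per day
  expect_true(all(table(tr$traces$animal_id, tr$traces$day_index) == 1))
  # chamber assignment within a day x run is a permutation of chambers
  by_run <- split(tr$traces$chamber_id,
                  paste(tr$traces$day_index, tr$traces$run_index))
  expect_true(all(vapply(by_run, function(ch)
    all(sort(ch) == seq_along(ch)), logical(1))))
  # truth decomposition is exact
  expect_equal(tr$truth$true_flux_lph,
               unname(tr$params$mean_flux[tr$truth$gas]) +
                 tr$truth$animal_effect + tr$truth$day_effect +
                 tr$truth$residual)
})

test_that("identical seed reproduces the trial; different seed does not", {
  t1 <- simulate_trial(sim_params(seed = 11), small_design())
  t2 <- simulate_trial(sim_params(seed = 11), small_design())
  t3 <- simulate_trial(sim_params(seed = 12), small_design())
  expect_identical(t1$traces, t2$traces)
  expect_identical(t1$truth, t2$truth)
  expect_false(isTRUE(all.equal(t1$truth$true_flux_lph,
                                t3$truth$true_flux_lph)))
})

test_that("between-animal variance of animal means matches the law of total variance", {
  # day effects are shared by all animals within a trial, so they cancel
  # from the between-animal variance of per-animal means: the expectation
  # is s2_animal + s2_error / n_days. Checked against an independent
  # brute-force generator as well as the trial generator.
  s2 <- unname(oxygen_var_truth)
  nd <- 8L
  expected <- s2[1] + s2[3] / nd
  reps <- 300L
  v_gen <- vapply(seq_len(reps), function(r) {
    tr <- simulate_trial(
      sim_params(seed = 20000 + r),
      trial_design(n_animals = 24, n_days = nd, n_runs_per_day = 4,
                   n_chambers = 6),
      gases = "O2"
    )
    tt <- tr$truth
    var(tapply(tt$true_flux_lph, tt$animal_id, mean))
  }, numeric(1))
  expect_lt(abs(mean(v_gen) - expected) / expected, 0.05)
  # independent oracle: raw normal draws, same statistic
  set.seed(99)
  v_oracle <- vapply(seq_len(reps), function(r) {
    y <- rnorm(24, 0, sqrt(s2[1]))[rep(1:24, nd)] +
      rnorm(nd, 0, sqrt(s2[2]))[rep(1:nd, each = 24)] +
      rnorm(24 * nd, 0, sqrt(s2[3]))
    var(tapply(y, rep(1:24, nd), mean))
  }, numeric(1))
  expect_lt(abs(mean(v_oracle) - expected) / expected, 0.05)
})

test_that("physically impossible implied readings are rejected with a diagnostic", {
  p <- sim_params(mean_flux = c(CH4 = -0.01, O2 = 0.3582, CO2 = 0.2194),
                  var_animal = c(0, 0, 0), var_day = c(0, 0, 0),
                  var_error = c(0, 0, 0), seed = 1)
  expect_error(simulate_trial(p, small_design(), gases = "CH4"),
               "physically impossible.*animal A001.*day 1")
})

test_that("write -> read roundtrip preserves the trial numerically", {
  tr <- simulate_trial(sim_params(seed = 8), small_design())
  dir <- withr::local_tempdir()
  write_trial(tr, dir)
  back <- read_trial(dir)
  expect_identical(back$traces$ch4_ppm_t2, tr$traces$ch4_ppm_t2)
  expect_identical(back$traces$o2_pct_t1, tr$traces$o2_pct_t1)
  expect_identical(back$truth$true_flux_lph, tr$truth$true_flux_lph)
  expect_equal(nrow(back$truth), 12 * 6 * 3)
  # omitting the truth file still yields a valid analysis input
  dir2 <- withr::local_tempdir()
  write_trial(tr, dir2, truth = FALSE)
  back2 <- read_trial(dir2)
  expect_null(back2$truth)
  expect_s3_class(flux_table(back2), "data.frame")
})

test_that("time jitter and reading noise stay on their own random streams", {
  base <- simulate_trial(sim_params(seed = 5), small_design(), gases = "O2")
  noisy <- simulate_trial(
    sim_params(seed = 5, reading_noise = c(CH4 = 0, O2 = 0.005, CO2 = 0)),
    small_design(), gases = "O2"
  )
  # same underlying truth, different readings
  expect_identical(base$truth$true_flux_lph, noisy$truth$true_flux_lph)
  expect_false(identical(base$traces$o2_pct_t2, noisy$traces$o2_pct_t2))
  jit <- simulate_trial(sim_params(seed = 5, time_jitter = 2),
                        small_design(), gases = "O2")
  expect_identical(base$truth$true_flux_lph, jit$truth$true_flux_lph)
  expect_false(identical(base$traces$t1_min, jit$traces$t1_min))
  expect_true(all(diff(t(as.matrix(jit$traces[c("t0_min", "t1_min",
                                                "t2_min")]))) > 0))
})

test_that("parameter validation catches impossible settings", {
  expect_error(sim_params(baseline = c(CH4 = 2, O2 = 25, CO2 = 0.04)),
               "O2 baseline")
  expect_error(sim_params(var_animal = c(-1, 0.0056, 0.0014)))
  expect_error(trial_design(reading_times = c(0, 50, 25)),
               "strictly increasing")
  expect_error(trial_design(n_animals = 49), "cannot seat")
})
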