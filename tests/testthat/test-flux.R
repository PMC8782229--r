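test_that("trace-to-flux conversion matches the printed two-point equation", {
  # inverse-derived worked example: a 9.706 ppm rise over 50 min in a
  # (853 - 46) l net volume is a 0.0094 l/h methane flux
  r <- trace_to_flux_lph(c(2, 2 + 9.706 / 2, 11.706), c(0, 25, 50), "CH4", 46)
  expect_equal(r$flux_lph, (9.706 / 50 * 60) * (853 - 46) / 1e6)
  expect_equal(round(r$flux_lph, 4), 0.0094)
  expect_identical(r$qc_flags, "")
  # flat traces give zero flux
  expect_equal(trace_to_flux_lph(c(5, 5, 5), c(0, 25, 50), "CH4", 46)$flux_lph, 0)
  expect_equal(
    trace_to_flux_lph(c(20.9, 20.9, 20.9), c(0, 25, 50), "O2", 46)$flux_lph, 0)
})

test_that("sign conventions: production positive for CH4/CO2, consumption positive for O2", {
  up <- c(0.04, 0.055, 0.07)
  down <- c(20.9, 20.88, 20.86)
  expect_gt(trace_to_flux_lph(up, c(0, 25, 50), "CO2", 46)$flux_lph, 0)
  expect_gt(trace_to_flux_lph(down, c(0, 25, 50), "O2", 46)$flux_lph, 0)
  # declining CH4 is a negative flux: preserved and flagged, not clamped
  r <- trace_to_flux_lph(c(11.7, 7, 2), c(0, 25, 50), "CH4", 46)
  expect_lt(r$flux_lph, 0)
  expect_match(r$qc_flags, "negative_flux")
})

test_that("conversion is linear in the concentration change and net volume", {
  base <- trace_to_flux_lph(c(2, 6, 10), c(0, 25, 50), "CH4", 46)$flux_lph
  dbl <- trace_to_flux_lph(c(2, 10, 18), c(0, 25, 50), "CH4", 46)$flux_lph
  expect_equal(dbl, 2 * base)
  half_vol <- trace_to_flux_lph(c(2, 6, 10), c(0, 25, 50), "CH4", 46,
                                chamber_volume = (853 + 46) / 2)$flux_lph
  expect_equal(half_vol / base, ((853 + 46) / 2 - 46) / (853 - 46))
})

test_that("nonlinear traces are flagged and invalid traces rejected", {
  bent <- trace_to_flux_lph(c(2, 9, 10), c(0, 25, 50), "CH4", 46)
  expect_match(bent$qc_flags, "nonlinear_trace")
  expect_error(trace_to_flux_lph(c(2, 6, 10), c(0, 25, 25), "CH4", 46),
               "strictly increasing")
  expect_error(trace_to_flux_lph(c(2, 6, 10), c(0, 25, 50), "CH4", 900),
               "net free volume")
  expect_error(trace_to_flux_lph(c(-1, 6, 10), c(0, 25, 50), "CH4", 46),
               ">= 0")
  expect_error(trace_to_flux_lph(c(2, 6, 10), c(0, 25, 50), "N2O", 46))
})

test_that("g/d extrapolation follows the ideal-gas formula verbatim", {
  expect_equal(flux_lph_to_gpd(0, 8.33, 1000.05, "CH4"), 0)
  # independent arithmetic of the printed formula
  k <- 1000.05 * 0.1 / (8.3145 * (8.33 + 273.15))
  expect_equal(flux_lph_to_gpd(0.0094, 8.33, 1000.05, "CH4"),
               0.0094 * k * 16 * 1440)
  expect_equal(flux_lph_to_gpd(0.2194, 8.33, 1000.05, "CO2"),
               0.2194 * k * 44 * 1440)
  expect_equal(flux_lph_to_gpd(0.3582, 8.33, 1000.05, "O2"),
               0.3582 * k * 32 * 1440)
})

test_that("g/d extrapolation is monotone in pressure and temperature", {
  pr <- seq(950, 1050, by = 10)
  expect_true(all(diff(flux_lph_to_gpd(0.01, 10, pr, "CH4")) > 0))
  tp <- seq(-5, 30, by = 5)
  expect_true(all(diff(flux_lph_to_gpd(0.01, tp, 1000, "CH4")) < 0))
  expect_error(flux_lph_to_gpd(0.01, -300, 1000, "CH4"))
})

test_that("flux_table recovers generating fluxes and excludes invalid rows", {
  tr <- fixture_trial()
  fx <- fixture_flux()
  expect_equal(nrow(fx), 48 * 17 * 3)
  m <- merge(fx, tr$truth, by = c("animal_id", "day_index", "gas"))
  expect_lt(max(abs(m$flux_lph - m$true_flux_lph)), 1e-10)
  # corrupt one row: it is excluded with a reason, the rest processed
  traces <- tr$traces
  traces$t1_min[5] <- traces$t0_min[5]
  expect_message(fx2 <- flux_table(traces), "excluded 1 of 816")
  expect_equal(nrow(fx2), 815 * 3)
  excl <- attr(fx2, "excluded")
  expect_equal(nrow(excl), 1)
  expect_match(excl$reason, "non-increasing")
  expect_error(flux_table(traces[0, ]), "empty")
})

test_that("flux_table agrees with the scalar trace conversion row by row", {
  tr <- fixture_trial()
  fx <- fixture_flux()
  reading_cols <- list(CH4 = c("ch4_ppm_t0", "ch4_ppm_t1", "ch4_ppm_t2"),
                       O2 = c("o2_pct_t0", "o2_pct_t1", "o2_pct_t2"),
                       CO2 = c("co2_pct_t0", "co2_pct_t1", "co2_pct_t2"))
  set.seed(3)
  for (i in sample(nrow(tr$traces), 25)) {
    row <- tr$traces[i, ]
    for (g in pac_gases()) {
      ref <- trace_to_flux_lph(as.numeric(row[reading_cols[[g]]]),
                               as.numeric(row[c("t0_min", "t1_min", "t2_min")]),
                               g, row$liveweight_kg)
      got <- fx[fx$animal_id == row$animal_id &
                  fx$day_index == row$day_index & fx$gas == g, ]
      expect_equal(got$flux_lph, ref$flux_lph)
      expect_identical(got$qc_flags, ref$qc_flags)
    }
  }
})

test_that("g/d column uses each record's own ambient conditions", {
  fx <- fixture_flux()
  i <- which(fx$gas == "CO2")[1:20]
  expect_equal(fx$flux_gpd[i],
               flux_lph_to_gpd(fx$flux_lph[i], fx$temp_c[i],
                               fx$pressure_hpa[i], "CO2"))
})
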