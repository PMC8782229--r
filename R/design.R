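#' Gases handled by the pipeline
#'
#' Canonical gas identifiers used throughout: methane (`"CH4"`, measured in
#' ppm), oxygen (`"O2"`, measured in %, reported as consumption) and carbon
#' dioxide (`"CO2"`, measured in %).
#'
#' @return Character vector of the three gas identifiers.
#' @export
pac_gases <- function() c("CH4", "O2", "CO2")

#' Trial design for a PAC measurement experiment
#'
#' Describes the layout of a portable-accumulation-chamber (PAC) trial:
#' how many animals are measured, over how many consecutive days, in how many
#' measurement runs per day, with how many chambers, and at which nominal
#' times the three gas readings are taken after animal entry.
#'
#' Defaults reproduce the study layout the package emulates: 48 ewe lambs
#' measured on 17 consecutive days in 4 runs/day of 12 chambers (853 l
#' internal volume), with readings at 0, 25 and 50 min.
#'
#' @param n_animals Number of animals.
#' @param n_days Number of consecutive measurement days.
#' @param n_runs_per_day Measurement runs per day.
#' @param n_chambers Number of chambers available per run.
#' @param chamber_volume Internal chamber volume in liters.
#' @param reading_times Strictly increasing numeric triple, minutes after
#'   animal entry, at which concentrations are read.
#'
#' @return An object of class `pac_design` (a validated list).
#' @export
trial_design <- function(n_animals = 48L,
                         n_days = 17L,
                         n_runs_per_day = 4L,
                         n_chambers = 12L,
                         chamber_volume = 853,
                         reading_times = c(0, 25, 50)) {
  d <- list(
    n_animals = as.integer(n_animals),
    n_days = as.integer(n_days),
    n_runs_per_day = as.integer(n_runs_per_day),
    n_chambers = as.integer(n_chambers),
    chamber_volume = as.numeric(chamber_volume),
    reading_times = as.numeric(reading_times)
  )
  stopifnot(
    d$n_animals >= 1L, d$n_days >= 1L,
    d$n_runs_per_day >= 1L, d$n_chambers >= 1L,
    d$chamber_volume > 0,
    length(d$reading_times) == 3L
  )
  if (any(diff(d$reading_times) <= 0)) {
    stop("reading_times must be strictly increasing")
  }
  if (d$n_animals > d$n_runs_per_day * d$n_chambers) {
    stop("design cannot seat ", d$n_animals, " animals in ",
         d$n_runs_per_day, " runs x ", d$n_chambers, " chambers")
  }
  structure(d, class = "pac_design")
}

#' Simulation parameters for a synthetic PAC trial
#'
#' Generating parameters for [simulate_trial()]. Per gas, the true flux of
#' animal i on day j is `mu + a_i + d_j + e_ij` with independent normal
#' animal, day and residual effects; effects are drawn independently across
#' gases. Defaults are the study conditions the package emulates: mean
#' fluxes and variance components from the published variance-component
#' table, liveweight 46 +/- 4.0 kg, ambient conditions 8.33 +/- 2.45 degC,
#' 1000.05 +/- 15.79 hPa, 76.68 +/- 8.66 % relative humidity. The oxygen
#' flux is a consumption (positive when O2 declines in the chamber).
#'
#' Ambient chamber baselines at entry default to typical outdoor air
#' (CH4 2.0 ppm, O2 20.9 %, CO2 0.04 %); only concentration differences
#' enter the flux equations, so baselines do not affect downstream
#' statistics.
#'
#' @param mean_flux Named numeric, mean flux per gas in l/h.
#' @param var_animal,var_day,var_error Named numeric, per-gas variance
#'   components in (l/h)^2.
#' @param liveweight_mean,liveweight_sd Liveweight distribution, kg. One
#'   weight is drawn per animal and held constant across days.
#' @param temp_mean,temp_sd Ambient temperature, degC, drawn per run.
#' @param pressure_mean,pressure_sd Atmospheric pressure, hPa, drawn per run.
#' @param humidity_mean,humidity_sd Relative humidity, %, drawn per run.
#' @param baseline Named numeric: chamber-entry concentrations (CH4 ppm,
#'   O2 %, CO2 %). The O2 baseline must not exceed 20.95 %.
#' @param reading_noise Named numeric, instrument noise SD added to each
#'   reading (ppm for CH4, percentage points for O2/CO2). Default 0: the
#'   instrument's reading-level precision is not reported, so traces are
#'   exact by default and noise is opt-in.
#' @param time_jitter Half-width (min) of uniform jitter applied to the
#'   recorded reading times around their nominal values; 0 keeps nominal
#'   times.
#' @param breeds Character vector of breed labels sampled uniformly per
#'   animal (labels only; breed has no effect on simulated fluxes).
#' @param age_range Age range in months, sampled uniformly per animal.
#' @param seed Master integer seed; sub-seeds for each stochastic component
#'   are derived from it (see [simulate_trial()]).
#'
#' @return An object of class `pac_params` (a validated list).
#' @export
sim_params <- function(mean_flux = c(CH4 = 0.0094, O2 = 0.3582, CO2 = 0.2194),
                       var_animal = c(CH4 = 0.0000018, O2 = 0.0056, CO2 = 0.0014),
                       var_day = c(CH4 = 0.0000030, O2 = 0.0069, CO2 = 0.0023),
                       var_error = c(CH4 = 0.0000077, O2 = 0.0051, CO2 = 0.0021),
                       liveweight_mean = 46, liveweight_sd = 4.0,
                       temp_mean = 8.33, temp_sd = 2.45,
                       pressure_mean = 1000.05, pressure_sd = 15.79,
                       humidity_mean = 76.68, humidity_sd = 8.66,
                       baseline = c(CH4 = 2.0, O2 = 20.9, CO2 = 0.04),
                       reading_noise = c(CH4 = 0, O2 = 0, CO2 = 0),
                       time_jitter = 0,
                       breeds = c("Suffolk", "Texel", "Belclare"),
                       age_range = c(10, 11),
                       seed = 1L) {
  gases <- pac_gases()
  as_gas_vec <- function(x, what) {
    if (is.null(names(x)) && length(x) == 3L) names(x) <- gases
    if (!all(gases %in% names(x))) {
      stop(what, " must be named with all of: ", paste(gases, collapse = ", "))
    }
    as.numeric(x[gases]) |> stats::setNames(gases)
  }
  p <- list(
    mean_flux = as_gas_vec(mean_flux, "mean_flux"),
    var_animal = as_gas_vec(var_animal, "var_animal"),
    var_day = as_gas_vec(var_day, "var_day"),
    var_error = as_gas_vec(var_error, "var_error"),
    liveweight_mean = as.numeric(liveweight_mean),
    liveweight_sd = as.numeric(liveweight_sd),
    temp_mean = as.numeric(temp_mean), temp_sd = as.numeric(temp_sd),
    pressure_mean = as.numeric(pressure_mean),
    pressure_sd = as.numeric(pressure_sd),
    humidity_mean = as.numeric(humidity_mean),
    humidity_sd = as.numeric(humidity_sd),
    baseline = as_gas_vec(baseline, "baseline"),
    reading_noise = as_gas_vec(reading_noise, "reading_noise"),
    time_jitter = as.numeric(time_jitter),
    breeds = as.character(breeds),
    age_range = as.numeric(age_range),
    seed = as.integer(seed)
  )
  stopifnot(
    all(p$var_animal >= 0), all(p$var_day >= 0), all(p$var_error >= 0),
    all(p$reading_noise >= 0),
    p$liveweight_sd >= 0, p$time_jitter >= 0,
    length(p$age_range) == 2L, p$age_range[1] <= p$age_range[2],
    length(p$breeds) >= 1L
  )
  if (p$baseline["O2"] > 20.95) {
    stop("O2 baseline exceeds the atmospheric mole fraction (20.95 %)")
  }
  if (p$baseline["CH4"] < 0 || p$baseline["CO2"] < 0) {
    stop("gas baselines must be non-negative")
  }
  structure(p, class = "pac_params")
}

#' @export
print.pac_design <- function(x, ...) {
  cat("PAC trial design:", x$n_animals, "animals x", x$n_days, "days,",
      x$n_runs_per_day, "runs/day x", x$n_chambers, "chambers (",
      x$chamber_volume, "l ), readings at",
      paste(x$reading_times, collapse = "/"), "min\n")
  invisible(x)
}

#' @export
print.pac_params <- function(x, ...) {
  cat("PAC simulation parameters (seed", x$seed, ")\n")
  m <- rbind(mean_flux = x$mean_flux, var_animal = x$var_animal,
             var_day = x$var_day, var_error = x$var_error)
  print(m)
  invisible(x)
}
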