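#' Physical constants used in the flux equations
#'
#' @return Named list: universal gas constant `R` (J/mol/K), molar masses
#'   (g/mol), minutes per day, the hPa-to-kPa factor, the Celsius-to-Kelvin
#'   offset, and the concentration-scale divisor per gas (1e6 for ppm-scale
#'   CH4, 100 for %-scale O2 and CO2).
#' @export
gas_constants <- function() {
  list(
    R = 8.3145,
    molar_mass = c(CH4 = 16, CO2 = 44, O2 = 32),
    min_per_day = 1440,
    hpa_to_kpa = 0.1,
    c_to_k = 273.15,
    conc_divisor = c(CH4 = 1e6, O2 = 100, CO2 = 100)
  )
}

#' Convert a three-point chamber trace to a volumetric flux (l/h)
#'
#' Implements the two-point accumulation-chamber conversion
#' `flux = ((C_x - C_y) / (T_x - T_y) * 60) * (V - liveweight) / D`,
#' where D is 1e6 for ppm-scale CH4 and 100 for %-scale O2/CO2 and the net
#' free volume is the chamber volume minus the animal's liveweight (kg read
#' as liters displaced, exactly as the conversion is defined). For CH4 and
#' CO2 (produced gases) `(x, y)` is (last, first) reading; for O2 (consumed)
#' it is (first, last), so that normal physiology yields a positive value.
#'
#' The first and last readings and their actual recorded times define the
#' slope; the middle reading is used only for a linearity quality flag: it
#' is compared against the chord midpoint and flagged when the deviation
#' exceeds `lin_tol` times the absolute first-to-last concentration change.
#' Negative fluxes are returned unaltered and flagged, not clamped.
#'
#' @param readings Numeric triple of concentrations (ppm for CH4, % for
#'   O2/CO2) in time order.
#' @param times Numeric triple of recorded reading times (min), strictly
#'   increasing.
#' @param gas One of `"CH4"`, `"O2"`, `"CO2"`.
#' @param liveweight Animal liveweight, kg; must be below `chamber_volume`.
#' @param chamber_volume Chamber internal volume, liters (default 853).
#' @param lin_tol Relative tolerance for the mid-reading linearity flag.
#'
#' @return List with `flux_lph` and a character `qc_flags` string
#'   (comma-separated; empty when clean: possible flags `negative_flux`,
#'   `nonlinear_trace`).
#' @export
trace_to_flux_lph <- function(readings, times, gas, liveweight,
                              chamber_volume = 853, lin_tol = 0.05) {
  gas <- match.arg(gas, pac_gases())
  stopifnot(length(readings) == 3L, length(times) == 3L,
            is.finite(readings), is.finite(times))
  if (any(diff(times) <= 0)) stop("reading times must be strictly increasing")
  if (liveweight >= chamber_volume) {
    stop("liveweight (", liveweight, " kg) must be below the chamber volume (",
         chamber_volume, " l): net free volume would be non-positive")
  }
  if (gas == "CH4" && any(readings < 0)) stop("CH4 readings (ppm) must be >= 0")
  if (gas != "CH4" && (any(readings < 0) || any(readings > 100))) {
    stop(gas, " readings (%) must lie in [0, 100]")
  }
  k <- gas_constants()
  # concentration difference (x - y): (last - first) for produced CH4/CO2,
  # (first - last) for consumed O2, over the elapsed time, so that normal
  # physiology yields a positive flux for every gas
  dc <- if (gas == "O2") readings[1] - readings[3] else readings[3] - readings[1]
  flux <- (dc / (times[3] - times[1]) * 60) *
    (chamber_volume - liveweight) / k$conc_divisor[[gas]]
  flags <- character()
  if (flux < 0) flags <- c(flags, "negative_flux")
  chord_mid <- readings[1] +
    (readings[3] - readings[1]) * (times[2] - times[1]) / (times[3] - times[1])
  span <- abs(readings[3] - readings[1])
  if (span > 0 && abs(readings[2] - chord_mid) > lin_tol * span) {
    flags <- c(flags, "nonlinear_trace")
  }
  list(flux_lph = unname(flux), qc_flags = paste(flags, collapse = ","))
}

#' Extrapolate a volumetric flux (l/h) to daily mass output (g/d)
#'
#' Ideal-gas extrapolation evaluated exactly as the PAC protocol defines it:
#' `g/d = flux * (pressure * 0.1) / (8.3145 * (temperature + 273.15)) *
#' molar_mass * 1440`. The formula mixes an hourly flux with the 1440
#' min/day factor; it is applied verbatim because it is the form under
#' which the protocol's published daily values are defined (see the methods
#' vignette for the unit discussion).
#'
#' @param flux_lph Volumetric flux in l/h (vectorised).
#' @param temperature Ambient temperature, degC (> -273.15).
#' @param pressure Atmospheric pressure, hPa (> 0).
#' @param gas One of `"CH4"`, `"O2"`, `"CO2"`.
#'
#' @return Daily gas mass in g/d, same sign as `flux_lph`.
#' @export
flux_lph_to_gpd <- function(flux_lph, temperature, pressure, gas) {
  gas <- match.arg(gas, pac_gases())
  stopifnot(all(temperature > -273.15), all(pressure > 0))
  k <- gas_constants()
  flux_lph * (pressure * k$hpa_to_kpa) /
    (k$R * (temperature + k$c_to_k)) *
    k$molar_mass[[gas]] * k$min_per_day
}

#' Compute the per-gas flux table of a trial
#'
#' Applies [trace_to_flux_lph()] and [flux_lph_to_gpd()] to every
#' animal-day record of a trial trace table, yielding one row per
#' animal x day x gas. Rows violating the trace invariants (non-increasing
#' times, out-of-range readings, liveweight at or above the chamber volume,
#' non-finite values) are excluded from the output and collected, with
#' reasons, in the `"excluded"` attribute; a message reports how many were
#' dropped.
#'
#' @param trial A `pac_trial` from [simulate_trial()]/[read_trial()], or a
#'   trace data frame in the trial CSV layout.
#' @param chamber_volume Chamber volume (l); taken from the trial design
#'   when a `pac_trial` is given.
#' @param lin_tol Linearity-flag tolerance passed to [trace_to_flux_lph()].
#'
#' @return Data frame with columns `animal_id`, `day_index`, `gas`,
#'   `flux_lph`, `flux_gpd`, `qc_flags`, plus the covariates carried from
#'   the trace table (`run_index`, `chamber_id`, `breed`, `age_months`,
#'   `liveweight_kg`, `temp_c`, `pressure_hpa`, `humidity_pct`). Attribute
#'   `"excluded"` holds the rejected rows and reasons.
#' @export
flux_table <- function(trial, chamber_volume = NULL, lin_tol = 0.05) {
  if (inherits(trial, "pac_trial")) {
    traces <- trial$traces
    if (is.null(chamber_volume)) chamber_volume <- trial$design$chamber_volume
  } else {
    traces <- as.data.frame(trial)
    if (is.null(chamber_volume)) chamber_volume <- 853
  }
  if (nrow(traces) == 0L) stop("empty trace table")

  reading_cols <- list(
    CH4 = c("ch4_ppm_t0", "ch4_ppm_t1", "ch4_ppm_t2"),
    O2  = c("o2_pct_t0", "o2_pct_t1", "o2_pct_t2"),
    CO2 = c("co2_pct_t0", "co2_pct_t1", "co2_pct_t2")
  )
  time_cols <- c("t0_min", "t1_min", "t2_min")
  needed <- c("animal_id", "day_index", "liveweight_kg", time_cols)
  missing_cols <- setdiff(needed, names(traces))
  if (length(missing_cols)) {
    stop("trace table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  gases <- names(reading_cols)[vapply(reading_cols, function(cc)
    all(cc %in% names(traces)), logical(1))]
  if (length(gases) == 0L) stop("trace table has no gas reading columns")
  reading_cols <- reading_cols[gases]

  # row-level validation, one reason per failing row
  reason <- rep(NA_character_, nrow(traces))
  tm <- as.matrix(traces[time_cols])
  rd <- as.matrix(traces[unlist(reading_cols)])
  bad_finite <- !is.finite(traces$liveweight_kg) |
    rowSums(!is.finite(tm)) > 0 | rowSums(!is.finite(rd)) > 0
  reason[bad_finite] <- "non-finite value"
  bad_times <- is.na(reason) & (tm[, 2] <= tm[, 1] | tm[, 3] <= tm[, 2])
  reason[bad_times] <- "non-increasing reading times"
  bad_lw <- is.na(reason) & traces$liveweight_kg >= chamber_volume
  reason[bad_lw] <- "net volume non-positive (liveweight >= chamber volume)"
  if ("CH4" %in% gases) {
    ch4 <- as.matrix(traces[reading_cols$CH4])
    bad_ch4 <- is.na(reason) & rowSums(ch4 < 0) > 0
    reason[bad_ch4] <- "negative CH4 reading"
  }
  pct_cols <- unlist(reading_cols[intersect(c("O2", "CO2"), gases)])
  if (length(pct_cols)) {
    pct <- as.matrix(traces[pct_cols])
    bad_pct <- is.na(reason) & (rowSums(pct < 0) > 0 | rowSums(pct > 100) > 0)
    reason[bad_pct] <- "percentage reading outside [0, 100]"
  }

  excluded <- traces[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- reason[!is.na(reason)]
    message("flux_table: excluded ", nrow(excluded), " of ", nrow(traces),
            " rows (", paste(unique(excluded$reason), collapse = "; "), ")")
  }
  ok <- traces[is.na(reason), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no valid trace rows remain after validation")

  covars <- intersect(
    c("run_index", "chamber_id", "breed", "age_months", "liveweight_kg",
      "temp_c", "pressure_hpa", "humidity_pct"),
    names(ok)
  )
  k <- gas_constants()
  out <- do.call(rbind, lapply(gases, function(g) {
    # vectorised form of trace_to_flux_lph() over all rows (identical
    # arithmetic; the scalar function remains the reference definition)
    c0 <- ok[[reading_cols[[g]][1]]]
    c1 <- ok[[reading_cols[[g]][2]]]
    c2 <- ok[[reading_cols[[g]][3]]]
    t0 <- ok$t0_min; t1 <- ok$t1_min; t2 <- ok$t2_min
    dc <- if (g == "O2") c0 - c2 else c2 - c0
    flux <- (dc / (t2 - t0) * 60) *
      (chamber_volume - ok$liveweight_kg) / k$conc_divisor[[g]]
    chord_mid <- c0 + (c2 - c0) * (t1 - t0) / (t2 - t0)
    span <- abs(c2 - c0)
    nonlin <- span > 0 & abs(c1 - chord_mid) > lin_tol * span
    flags <- character(length(flux))
    flags[flux < 0] <- "negative_flux"
    flags[nonlin] <- ifelse(flags[nonlin] == "", "nonlinear_trace",
                            paste0(flags[nonlin], ",nonlinear_trace"))
    gpd <- if (all(c("temp_c", "pressure_hpa") %in% names(ok))) {
      flux_lph_to_gpd(flux, ok$temp_c, ok$pressure_hpa, g)
    } else {
      rep(NA_real_, length(flux))
    }
    cbind(
      data.frame(
        animal_id = ok$animal_id,
        day_index = ok$day_index,
        gas = g,
        flux_lph = flux,
        flux_gpd = gpd,
        qc_flags = flags,
        stringsAsFactors = FALSE
      ),
      ok[covars]
    )
  }))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
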