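#' Simulate a synthetic PAC trial
#'
#' Generates a complete portable-accumulation-chamber trial with the additive
#' variance structure assumed by the downstream variance-component models.
#' Per gas, animal effects `a_i ~ N(0, var_animal)`, day effects
#' `d_j ~ N(0, var_day)` and residuals `e_ij ~ N(0, var_error)` are drawn
#' independently (and independently across gases); the true flux of animal i
#' on day j is `mu + a_i + d_j + e_ij`. Three-point chamber traces are then
#' constructed by inverting the flux equations ([trace_to_flux_lph()]):
#' concentrations accumulate linearly from the ambient baseline, so feeding
#' the traces back through the flux conversion recovers the generating
#' fluxes to numerical round-off (when `reading_noise` is 0).
#'
#' Animals are reassigned to runs and chambers uniformly at random each day;
#' chamber assignment within a run is a permutation of the chambers.
#' Liveweight is drawn once per animal and held constant; ambient
#' temperature, pressure and humidity are drawn per day x run.
#'
#' Reproducibility: all draws derive from `params$seed` through fixed
#' per-component sub-seeds (animal attributes, animal/day/residual effects,
#' environment, chamber assignment, reading noise and time jitter each use
#' their own stream), so identical parameters give identical trials and
#' turning one noise source on does not perturb the others.
#'
#' @param params A `pac_params` object from [sim_params()].
#' @param design A `pac_design` object from [trial_design()].
#' @param gases Which gases to simulate (default all three). Single-gas
#'   trials are useful in replicate simulation studies of one trait.
#'
#' @return An object of class `pac_trial`: list with data frames `animals`,
#'   `environment`, `traces` (trial CSV layout, one row per animal x day),
#'   `truth` (one row per animal x day x gas with the generating effects
#'   and true fluxes), plus the `params` and `design` used.
#' @export
simulate_trial <- function(params = sim_params(), design = trial_design(),
                           gases = pac_gases()) {
  stopifnot(inherits(params, "pac_params"), inherits(design, "pac_design"))
  gases <- match.arg(gases, pac_gases(), several.ok = TRUE)
  na <- design$n_animals
  nd <- design$n_days
  sub_seed <- function(offset) {
    as.integer((as.numeric(params$seed) * 1009 + offset * 9973) %% 2147483629)
  }

  # animal attributes
  set.seed(sub_seed(1L))
  animals <- data.frame(
    animal_id = sprintf("A%03d", seq_len(na)),
    breed = sample(params$breeds, na, replace = TRUE),
    age_months = round(stats::runif(na, params$age_range[1], params$age_range[2]), 1),
    liveweight_kg = round(stats::rnorm(na, params$liveweight_mean,
                                       params$liveweight_sd), 1),
    stringsAsFactors = FALSE
  )
  if (any(animals$liveweight_kg >= design$chamber_volume)) {
    stop("simulated liveweight at or above chamber volume; check parameters")
  }

  # random effects per gas (independent streams per component)
  set.seed(sub_seed(2L))
  a_eff <- vapply(gases, function(g)
    stats::rnorm(na, 0, sqrt(params$var_animal[[g]])), numeric(na))
  set.seed(sub_seed(3L))
  d_eff <- vapply(gases, function(g)
    stats::rnorm(nd, 0, sqrt(params$var_day[[g]])), numeric(nd))
  set.seed(sub_seed(4L))
  resid <- vapply(gases, function(g)
    stats::rnorm(na * nd, 0, sqrt(params$var_error[[g]])), numeric(na * nd))

  idx_a <- rep(seq_len(na), times = nd)   # animal index per animal-day row
  idx_d <- rep(seq_len(nd), each = na)    # day index per animal-day row
  truth <- do.call(rbind, lapply(seq_along(gases), function(k) {
    g <- gases[k]
    data.frame(
      animal_id = animals$animal_id[idx_a],
      day_index = idx_d,
      gas = g,
      animal_effect = a_eff[idx_a, k],
      day_effect = d_eff[idx_d, k],
      residual = resid[, k],
      true_flux_lph = params$mean_flux[[g]] + a_eff[idx_a, k] +
        d_eff[idx_d, k] + resid[, k],
      stringsAsFactors = FALSE
    )
  }))
  rownames(truth) <- NULL

  # per day x run environment
  set.seed(sub_seed(5L))
  nr <- design$n_runs_per_day
  environment <- data.frame(
    day_index = rep(seq_len(nd), each = nr),
    run_index = rep(seq_len(nr), times = nd),
    temp_c = round(stats::rnorm(nd * nr, params$temp_mean, params$temp_sd), 2),
    pressure_hpa = round(stats::rnorm(nd * nr, params$pressure_mean,
                                      params$pressure_sd), 2),
    humidity_pct = pmin(100, pmax(0, round(
      stats::rnorm(nd * nr, params$humidity_mean, params$humidity_sd), 2)))
  )

  # daily random allocation to runs and chambers
  set.seed(sub_seed(6L))
  alloc <- do.call(rbind, lapply(seq_len(nd), function(j) {
    ord <- sample.int(na)
    data.frame(
      day_index = j,
      animal = ord,
      run_index = rep(seq_len(nr), each = design$n_chambers)[seq_len(na)],
      chamber_id = rep(seq_len(design$n_chambers), times = nr)[seq_len(na)]
    )
  }))

  # recorded reading times (nominal, with optional uniform jitter)
  set.seed(sub_seed(7L))
  t_nom <- design$reading_times
  jit <- function(n) {
    if (params$time_jitter > 0) {
      stats::runif(n, -params$time_jitter, params$time_jitter)
    } else {
      rep(0, n)
    }
  }
  n_rec <- na * nd
  t0 <- pmax(0, t_nom[1] + jit(n_rec))
  t1 <- t_nom[2] + jit(n_rec)
  t2 <- t_nom[3] + jit(n_rec)
  if (any(t1 <= t0) || any(t2 <= t1)) {
    stop("time jitter too large: recorded times are not strictly increasing")
  }

  # trace construction: linear accumulation from the baseline, inverse of
  # the two-point flux equation over the recorded t0..t2 span
  k_const <- gas_constants()
  lw <- animals$liveweight_kg[idx_a]
  net_vol <- design$chamber_volume - lw
  set.seed(sub_seed(8L))
  readings <- list()
  for (g in gases) {
    fl <- truth$true_flux_lph[truth$gas == g]
    delta <- fl * k_const$conc_divisor[[g]] * (t2 - t0) / 60 / net_vol
    c0 <- rep(params$baseline[[g]], n_rec)
    c2 <- if (g == "O2") c0 - delta else c0 + delta
    c1 <- c0 + (c2 - c0) * (t1 - t0) / (t2 - t0)
    if (params$reading_noise[[g]] > 0) {
      c0 <- c0 + stats::rnorm(n_rec, 0, params$reading_noise[[g]])
      c1 <- c1 + stats::rnorm(n_rec, 0, params$reading_noise[[g]])
      c2 <- c2 + stats::rnorm(n_rec, 0, params$reading_noise[[g]])
    }
    bad <- which(c0 < 0 | c1 < 0 | c2 < 0 |
                   (g != "CH4" & (c0 > 100 | c1 > 100 | c2 > 100)))
    if (length(bad)) {
      b <- bad[1]
      stop("physically impossible ", g, " reading implied for animal ",
           animals$animal_id[idx_a[b]], ", day ", idx_d[b],
           " (true flux ", signif(fl[b], 4),
           " l/h with baseline ", params$baseline[[g]], ")")
    }
    readings[[g]] <- cbind(c0, c1, c2)
  }

  traces <- data.frame(
    animal_id = animals$animal_id[idx_a],
    breed = animals$breed[idx_a],
    age_months = animals$age_months[idx_a],
    day_index = idx_d,
    run_index = NA_integer_,
    chamber_id = NA_integer_,
    liveweight_kg = lw,
    t0_min = t0, t1_min = t1, t2_min = t2,
    stringsAsFactors = FALSE
  )
  col_stub <- c(CH4 = "ch4_ppm", O2 = "o2_pct", CO2 = "co2_pct")
  for (g in gases) {
    for (s in 1:3) {
      traces[[paste0(col_stub[[g]], "_t", s - 1L)]] <- readings[[g]][, s]
    }
  }
  ord <- order(alloc$day_index, alloc$animal)
  alloc <- alloc[ord, ]
  stopifnot(all(alloc$animal == idx_a[order(idx_d, idx_a)]))
  key <- order(traces$day_index, match(traces$animal_id, animals$animal_id))
  traces$run_index[key] <- alloc$run_index
  traces$chamber_id[key] <- alloc$chamber_id
  env_key <- match(
    paste(traces$day_index, traces$run_index),
    paste(environment$day_index, environment$run_index)
  )
  traces$temp_c <- environment$temp_c[env_key]
  traces$pressure_hpa <- environment$pressure_hpa[env_key]
  traces$humidity_pct <- environment$humidity_pct[env_key]

  structure(
    list(animals = animals, environment = environment, traces = traces,
         truth = truth, params = params, design = design),
    class = "pac_trial"
  )
}

#' @export
print.pac_trial <- function(x, ...) {
  cat("Synthetic PAC trial:", x$design$n_animals, "animals x",
      x$design$n_days, "days (", nrow(x$traces), "animal-day records,",
      nrow(x$truth), "truth rows )\n")
  invisible(x)
}

#' Write a trial to CSV files
#'
#' Writes `trial.csv` (the long-format trace table, one row per animal x
#' day) and, unless `truth = FALSE`, `truth.csv` with the generating
#' effects and true fluxes for parameter-recovery checks. Omitting the
#' truth file still yields a complete analysis input.
#'
#' @param trial A `pac_trial`.
#' @param dir Output directory (created if needed).
#' @param truth Whether to also write `truth.csv`.
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(trial, dir, truth = TRUE) {
  stopifnot(inherits(trial, "pac_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "trial.csv")
  .write_csv_precise(trial$traces, paths)
  if (truth) {
    tp <- file.path(dir, "truth.csv")
    .write_csv_precise(trial$truth, tp)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

# CSV writer that serialises doubles with 17 significant digits so a
# write -> read cycle reproduces them bit for bit
.write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read a trial written by [write_trial()]
#'
#' @param dir Directory containing `trial.csv` (and optionally `truth.csv`),
#'   or a path to a trial CSV file directly.
#' @param chamber_volume Chamber volume (l) to attach to the design.
#' @return A `pac_trial` (with `params = NULL`; the design is reconstructed
#'   from the data).
#' @export
read_trial <- function(dir, chamber_volume = 853) {
  trial_path <- if (dir.exists(dir)) file.path(dir, "trial.csv") else dir
  if (!file.exists(trial_path)) stop("no trial CSV at ", trial_path)
  traces <- utils::read.csv(trial_path, stringsAsFactors = FALSE)
  truth_path <- file.path(dirname(trial_path), "truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  design <- trial_design(
    n_animals = length(unique(traces$animal_id)),
    n_days = length(unique(traces$day_index)),
    n_runs_per_day = max(1L, length(unique(traces$run_index))),
    n_chambers = max(1L, length(unique(traces$chamber_id))),
    chamber_volume = chamber_volume,
    reading_times = c(traces$t0_min[1], traces$t1_min[1], traces$t2_min[1])
  )
  structure(
    list(animals = unique(traces[c("animal_id", "breed", "age_months",
                                   "liveweight_kg")]),
         environment = unique(traces[c("day_index", "run_index", "temp_c",
                                       "pressure_hpa", "humidity_pct")]),
         traces = traces, truth = truth, params = NULL, design = design),
    class = "pac_trial"
  )
}
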