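#' Read and validate a pipeline configuration file
#'
#' The configuration is a YAML mapping with the schema below; unknown keys
#' anywhere in the file are rejected before any computation runs.
#'
#' ```yaml
#' seed: 1                  # master seed
#' gases: [CH4, O2, CO2]    # gases to analyse
#' out_dir: results         # where stage CSVs are written
#' input: null              # existing trial CSV; null -> simulate
#' design:                  # any trial_design() argument
#'   n_animals: 48
#' sim:                     # any sim_params() argument except seed
#'   liveweight_mean: 46
#' precision_targets: [0.05, 0.03]   # l/h, optional
#' ranking_k: 10
#' n_folds: 4
#' ```
#'
#' @param path Path to a YAML config file.
#' @return A validated config list of class `pac_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  pipeline_config(raw)
}

#' Build a pipeline configuration from a list
#'
#' @param config Named list following the schema of
#'   [read_pipeline_config()]; missing keys take defaults.
#' @return A validated `pac_config`.
#' @export
pipeline_config <- function(config = list()) {
  known <- c("seed", "gases", "out_dir", "input", "design", "sim",
             "precision_targets", "ranking_k", "n_folds")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- list(
    seed = as.integer(config$seed %||% 1L),
    gases = as.character(config$gases %||% pac_gases()),
    out_dir = config$out_dir %||% "results",
    input = config$input,
    design = config$design %||% list(),
    sim = config$sim %||% list(),
    precision_targets = as.numeric(config$precision_targets %||% numeric()),
    ranking_k = as.integer(config$ranking_k %||% 10L),
    n_folds = as.integer(config$n_folds %||% 4L)
  )
  if (!all(cfg$gases %in% pac_gases())) {
    stop("gases must be among: ", paste(pac_gases(), collapse = ", "))
  }
  bad_design <- setdiff(names(cfg$design), names(formals(trial_design)))
  if (length(bad_design)) {
    stop("unknown design key(s): ", paste(bad_design, collapse = ", "))
  }
  bad_sim <- setdiff(names(cfg$sim), setdiff(names(formals(sim_params)), "seed"))
  if (length(bad_sim)) {
    stop("unknown sim key(s): ", paste(bad_sim, collapse = ", "))
  }
  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    stop("input trial CSV not found: ", cfg$input)
  }
  structure(cfg, class = "pac_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a trial input table
#'
#' Row-level checks of the trace invariants (finite values, strictly
#' increasing reading times, readings in physical range, positive net
#' chamber volume), duplicate animal-day detection, and loose range checks
#' on the ambient covariates.
#'
#' @param trial A `pac_trial`, a trace data frame, or a path to a trial CSV.
#' @param chamber_volume Chamber volume (l).
#' @return List with `n_rows`, `n_pass`, `n_fail` and a `failures` data
#'   frame (row index + reason).
#' @export
validate_input <- function(trial, chamber_volume = 853) {
  traces <- if (inherits(trial, "pac_trial")) {
    trial$traces
  } else if (is.character(trial)) {
    read_trial(trial, chamber_volume)$traces
  } else {
    as.data.frame(trial)
  }
  fail <- list()
  add <- function(rows, reason) {
    if (length(rows)) fail[[length(fail) + 1L]] <<- data.frame(
      row = rows, reason = reason, stringsAsFactors = FALSE)
  }
  num_cols <- intersect(
    c("liveweight_kg", "t0_min", "t1_min", "t2_min",
      "ch4_ppm_t0", "ch4_ppm_t1", "ch4_ppm_t2",
      "o2_pct_t0", "o2_pct_t1", "o2_pct_t2",
      "co2_pct_t0", "co2_pct_t1", "co2_pct_t2",
      "temp_c", "pressure_hpa", "humidity_pct"),
    names(traces)
  )
  nm <- as.matrix(traces[num_cols])
  add(which(rowSums(!is.finite(nm)) > 0), "non-finite value")
  add(which(traces$t1_min <= traces$t0_min | traces$t2_min <= traces$t1_min),
      "non-increasing reading times")
  add(which(traces$liveweight_kg >= chamber_volume),
      "net volume non-positive")
  ch4_cols <- intersect(c("ch4_ppm_t0", "ch4_ppm_t1", "ch4_ppm_t2"),
                        names(traces))
  if (length(ch4_cols)) {
    ch4 <- as.matrix(traces[ch4_cols])
    add(which(rowSums(ch4 < 0) > 0), "negative CH4 reading")
  }
  pct_cols <- intersect(c("o2_pct_t0", "o2_pct_t1", "o2_pct_t2",
                          "co2_pct_t0", "co2_pct_t1", "co2_pct_t2"),
                        names(traces))
  if (length(pct_cols)) {
    pct <- as.matrix(traces[pct_cols])
    add(which(rowSums(pct < 0 | pct > 100) > 0),
        "percentage reading outside [0, 100]")
  }
  dup <- duplicated(traces[c("animal_id", "day_index")]) |
    duplicated(traces[c("animal_id", "day_index")], fromLast = TRUE)
  add(which(dup), "duplicated animal-day record")
  if ("temp_c" %in% names(traces)) {
    add(which(traces$temp_c < -40 | traces$temp_c > 50),
        "temperature outside plausible range")
  }
  if ("pressure_hpa" %in% names(traces)) {
    add(which(traces$pressure_hpa < 850 | traces$pressure_hpa > 1100),
        "pressure outside plausible range")
  }
  if ("humidity_pct" %in% names(traces)) {
    add(which(traces$humidity_pct < 0 | traces$humidity_pct > 100),
        "humidity outside [0, 100]")
  }
  failures <- if (length(fail)) {
    do.call(rbind, fail)
  } else {
    data.frame(row = integer(), reason = character())
  }
  list(
    n_rows = nrow(traces),
    n_pass = nrow(traces) - length(unique(failures$row)),
    n_fail = length(unique(failures$row)),
    failures = failures
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when no input trial is given) -> flux conversion ->
#' variance components (REML, plus the balanced-ANOVA closed form when the
#' layout allows) -> precision curves -> day-consistency -> cross-validated
#' prediction, writing every stage's CSV under `config$out_dir` together
#' with a `summary.yaml` echoing the configuration, seed and headline
#' numbers. Identical configuration and seed give identical outputs.
#'
#' @param config A `pac_config`, a config list, or a YAML file path.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pac_config")) config <- pipeline_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  trial <- stage("simulate", {
    if (is.null(config$input)) {
      message("simulate: synthetic trial (seed ", config$seed, ")")
      params <- do.call(sim_params, c(config$sim, list(seed = config$seed)))
      design <- do.call(trial_design, config$design)
      tr <- simulate_trial(params, design)
      write_trial(tr, out)
      tr
    } else {
      message("load: ", config$input)
      read_trial(config$input)
    }
  })

  vi <- stage("validate", validate_input(trial,
                                         trial$design$chamber_volume))
  if (vi$n_fail > 0) {
    message("validate: ", vi$n_fail, " of ", vi$n_rows, " rows flagged")
  }

  fx <- stage("flux", flux_table(trial))
  utils::write.csv(fx, file.path(out, "flux.csv"), row.names = FALSE)

  vc_list <- stage("varcomp", {
    lapply(stats::setNames(config$gases, config$gases), function(g) {
      fit_reml(fx, model_spec(g), se = TRUE)
    })
  })
  vc_df <- do.call(rbind, lapply(vc_list, function(v) data.frame(
    gas = v$spec$gas, estimator = v$estimator, mean_lph = v$mu,
    var_animal = v$sigma2[["animal"]], var_day = v$sigma2[["day"]],
    var_error = v$sigma2[["error"]],
    se_animal = v$se[["animal"]], se_day = v$se[["day"]],
    se_error = v$se[["error"]],
    H_ani = v$H_ani, CV = v$CV, repeatability = v$repeatability,
    logLik = v$logLik
  )))
  utils::write.csv(vc_df, file.path(out, "varcomp.csv"), row.names = FALSE)

  prec <- stage("precision", {
    do.call(rbind, lapply(vc_list, function(v)
      precision_curve(v$sigma2[["error"]], trial$design$n_days,
                      gas = v$spec$gas)))
  })
  utils::write.csv(prec, file.path(out, "precision.csv"), row.names = FALSE)

  cons <- stage("consistency", {
    lapply(stats::setNames(config$gases, config$gases), function(g) {
      list(matrix = day_correlation_matrix(fx, g),
           ranking = ranking_consistency(fx, g, config$ranking_k))
    })
  })
  for (g in config$gases) {
    utils::write.csv(cons[[g]]$matrix$correlation,
                     file.path(out, paste0("day_correlation_", g, ".csv")))
    utils::write.csv(cons[[g]]$ranking$per_animal,
                     file.path(out, paste0("ranking_", g, ".csv")),
                     row.names = FALSE)
  }

  cv_list <- stage("predict", {
    lapply(stats::setNames(config$gases, config$gases), function(g) {
      cross_validate(fx, prediction_spec(g, config$n_folds, config$seed))
    })
  })
  cv_df <- do.call(rbind, lapply(cv_list, `[[`, "summary"))
  utils::write.csv(cv_df, file.path(out, "prediction.csv"), row.names = FALSE)

  headline <- lapply(stats::setNames(config$gases, config$gases), function(g) {
    v <- vc_list[[g]]
    list(
      mean_lph = v$mu, H_ani_pct = 100 * v$H_ani,
      repeatability = v$repeatability,
      P7_lph = 1.96 * sqrt(v$sigma2[["error"]] / 7),
      cv_r2_mean = cv_list[[g]]$summary$r2_mean,
      cv_rmse_mean = cv_list[[g]]$summary$rmse_mean
    )
  })
  yaml::write_yaml(
    list(
      config = unclass(config),
      package_version = as.character(utils::packageVersion("pacflux")),
      validation = list(n_rows = vi$n_rows, n_fail = vi$n_fail),
      headline = headline
    ),
    file.path(out, "summary.yaml")
  )
  message("pipeline complete: outputs in ", out)
  invisible(list(trial = trial, validation = vi, flux = fx,
                 varcomp = vc_list, precision = prec, consistency = cons,
                 prediction = cv_list))
}
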