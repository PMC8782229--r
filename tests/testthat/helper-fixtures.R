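# Shared fixtures, all generated in code.

# one full default-size three-gas trial, built once per test run
fixture_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_trial(sim_params(seed = 2), trial_design())
    }
    cache
  }
})

fixture_flux <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- flux_table(fixture_trial())
    cache
  }
})

# direct crossed-design response generator, independent of simulate_trial:
# y_ij = mu + a_i + d_j + e_ij, returned as a minimal flux table
make_crossed_data <- function(n_animals, n_days, s2, mu = 10, seed = 1,
                              gas = "O2") {
  set.seed(seed)
  a <- rnorm(n_animals, 0, sqrt(s2[1]))
  d <- rnorm(n_days, 0, sqrt(s2[2]))
  e <- rnorm(n_animals * n_days, 0, sqrt(s2[3]))
  ia <- rep(seq_len(n_animals), times = n_days)
  id <- rep(seq_len(n_days), each = n_animals)
  data.frame(
    animal_id = sprintf("A%03d", ia),
    day_index = id,
    gas = gas,
    flux_lph = mu + a[ia] + d[id] + e,
    stringsAsFactors = FALSE
  )
}

# a small trial design that keeps REML fits cheap
small_design <- function(n_animals = 12L, n_days = 6L) {
  trial_design(n_animals = n_animals, n_days = n_days,
               n_runs_per_day = 3L, n_chambers = ceiling(n_animals / 3))
}

oxygen_var_truth <- c(animal = 0.0056, day = 0.0069, error = 0.0051)
co2_var_truth <- c(animal = 0.0014, day = 0.0023, error = 0.0021)
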