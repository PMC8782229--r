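#' Number-of-days precision curve
#'
#' Precision of an n-day average, defined as the 95% confidence-interval
#' range `P_n = 1.96 * sqrt(s2_error / n)` for n = 1..n_max days of
#' consecutive measurement. Both the full range `P_n` and the half range
#' `P_n / 2` (the "+/-" read) are reported, because published precision
#' values are quoted under both conventions depending on the gas (see the
#' methods vignette).
#'
#' @param sigma2_e Error (within-animal, between-day residual) variance of
#'   the flux, (l/h)^2.
#' @param n_max Largest number of days to tabulate (default 17).
#' @param gas Optional gas label carried into the output.
#' @return Data frame of class `pac_precision` with columns `gas`, `n`,
#'   `P_n`, `half_range` (both in l/h).
#' @export
precision_curve <- function(sigma2_e, n_max = 17L, gas = NA_character_) {
  stopifnot(sigma2_e >= 0, n_max >= 1L)
  n <- seq_len(n_max)
  p <- 1.96 * sqrt(sigma2_e / n)
  structure(
    data.frame(gas = gas, n = n, P_n = p, half_range = p / 2),
    class = c("pac_precision", "data.frame"),
    sigma2_e = sigma2_e
  )
}

#' Days of measurement needed to reach a target precision
#'
#' Smallest integer n with `P_n <= target`, i.e. the ceiling of
#' `1.96^2 * sigma2_e / target^2` (at least 1).
#'
#' @param sigma2_e Error variance, (l/h)^2.
#' @param target Target 95% CI range, l/h (> 0).
#' @return Integer day count.
#' @export
days_for_precision <- function(sigma2_e, target) {
  stopifnot(sigma2_e >= 0, all(target > 0))
  vapply(target, function(tg) {
    if (sigma2_e == 0) return(1L)
    n <- max(1L, as.integer(ceiling(1.96^2 * sigma2_e / tg^2)))
    # guard the ceiling against floating-point edge cases
    while (n > 1L && 1.96 * sqrt(sigma2_e / (n - 1L)) <= tg) n <- n - 1L
    while (1.96 * sqrt(sigma2_e / n) > tg) n <- n + 1L
    n
  }, integer(1))
}
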