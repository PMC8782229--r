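#' Pairwise day-to-day correlation, slope and R-squared matrices
#'
#' Reshapes a gas's fluxes to an animals x days matrix and computes, for
#' every pair of days, the Pearson correlation of animal fluxes
#' (pairwise-complete), the slope (with standard error) of regressing the
#' later day's flux on the earlier day's, and the simple-regression
#' R-squared (the squared correlation). A day with zero flux variance
#' yields `NA` entries for its pairs, with the reason recorded.
#'
#' @param flux_tab Flux table (see [flux_table()]).
#' @param gas Gas to analyse.
#' @param method Correlation method; Pearson is the default, Spearman
#'   available as a robustness option (slopes/SEs are always computed on
#'   the raw fluxes).
#' @return An object of class `pac_daymatrix`: list of day-by-day matrices
#'   `correlation`, `slope`, `slope_se`, `r_squared`, `n_pairs`, plus
#'   `degenerate_days` (days with zero variance) and the day labels.
#' @export
day_correlation_matrix <- function(flux_tab, gas,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  d <- flux_tab[flux_tab$gas == gas, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for gas ", gas)
  days <- sort(unique(d$day_index))
  animals <- sort(unique(d$animal_id))
  wide <- matrix(NA_real_, length(animals), length(days),
                 dimnames = list(animals, paste0("day", days)))
  wide[cbind(match(d$animal_id, animals), match(d$day_index, days))] <-
    d$flux_lph
  nd <- length(days)
  corr <- matrix(NA_real_, nd, nd, dimnames = list(days, days))
  slope <- corr; slope_se <- corr; r2 <- corr
  npairs <- matrix(0L, nd, nd, dimnames = list(days, days))
  var0 <- apply(wide, 2, stats::var, na.rm = TRUE)
  degenerate <- days[!is.na(var0) & var0 == 0]
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      ok <- stats::complete.cases(wide[, i], wide[, j])
      m <- sum(ok)
      npairs[i, j] <- m
      if (m < 2L) next
      xi <- wide[ok, i]; xj <- wide[ok, j]
      if (stats::var(xi) == 0 || stats::var(xj) == 0) next
      r <- stats::cor(xi, xj, method = method)
      corr[i, j] <- r
      b <- stats::cov(xi, xj) / stats::var(xi)   # regress day j on day i
      slope[i, j] <- b
      r_p <- stats::cor(xi, xj)                  # slope SE on raw scale
      slope_se[i, j] <- if (m > 2L) {
        sqrt((1 - r_p^2) / (m - 2)) * stats::sd(xj) / stats::sd(xi)
      } else {
        NA_real_
      }
      r2[i, j] <- stats::cor(xi, xj)^2
    }
  }
  structure(
    list(gas = gas, method = method, days = days,
         correlation = corr, slope = slope, slope_se = slope_se,
         r_squared = r2, n_pairs = npairs, degenerate_days = degenerate),
    class = "pac_daymatrix"
  )
}

#' @export
print.pac_daymatrix <- function(x, ...) {
  off <- x$correlation[upper.tri(x$correlation)]
  cat("Day-pair ", x$method, " correlations for ", x$gas, ": ",
      length(x$days), " days, mean off-diagonal r = ",
      signif(mean(off, na.rm = TRUE), 3), "\n", sep = "")
  if (length(x$degenerate_days)) {
    cat("days with zero variance (pairs undefined):",
        paste(x$degenerate_days, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Top/bottom-k ranking consistency across days
#'
#' Ranks animals by flux (ascending) within each day and accumulates, per
#' animal, on how many days it fell in the bottom k (lowest emitters) and
#' top k (highest emitters). Ties at the k-th boundary are broken by
#' stable animal-id order and the affected days are flagged. Fractions of
#' days are also reported as integer percentages (rounded to the nearest
#' percent).
#'
#' @param flux_tab Flux table.
#' @param gas Gas to analyse.
#' @param k Tail size (default 10); must be below the animal count.
#' @return An object of class `pac_ranking`: list with `per_animal` (counts
#'   and fractions), `per_day` (rank table), `tied_days`, `k`, `n_days`.
#' @export
ranking_consistency <- function(flux_tab, gas, k = 10L) {
  d <- flux_tab[flux_tab$gas == gas, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for gas ", gas)
  animals <- sort(unique(d$animal_id))
  days <- sort(unique(d$day_index))
  if (k >= length(animals)) stop("k must be below the number of animals")
  per_day <- lapply(days, function(j) {
    dj <- d[d$day_index == j, , drop = FALSE]
    if (nrow(dj) < k) stop("day ", j, " has fewer than k valid fluxes")
    ord <- order(dj$flux_lph, dj$animal_id)   # stable tie-break by id
    ranked <- dj$animal_id[ord]
    fl <- dj$flux_lph[ord]
    n <- length(ranked)
    tied <- (k < n && fl[k] == fl[k + 1]) ||
      (n - k >= 1 && fl[n - k] == fl[n - k + 1])
    list(day = j, ranked = ranked,
         bottom = ranked[seq_len(k)],
         top = ranked[seq.int(n - k + 1L, n)],
         tied = tied)
  })
  bottom_n <- vapply(animals, function(a)
    sum(vapply(per_day, function(p) a %in% p$bottom, logical(1))), integer(1))
  top_n <- vapply(animals, function(a)
    sum(vapply(per_day, function(p) a %in% p$top, logical(1))), integer(1))
  nd <- length(days)
  per_animal <- data.frame(
    animal_id = animals,
    days_bottom_k = bottom_n,
    days_top_k = top_n,
    frac_bottom_k = bottom_n / nd,
    frac_top_k = top_n / nd,
    pct_bottom_k = as.integer(round(100 * bottom_n / nd)),
    pct_top_k = as.integer(round(100 * top_n / nd)),
    stringsAsFactors = FALSE
  )
  rank_tab <- do.call(rbind, lapply(per_day, function(p)
    data.frame(day_index = p$day, rank = seq_along(p$ranked),
               animal_id = p$ranked, stringsAsFactors = FALSE)))
  structure(
    list(gas = gas, k = as.integer(k), n_days = nd,
         per_animal = per_animal, per_day = rank_tab,
         tied_days = days[vapply(per_day, `[[`, logical(1), "tied")]),
    class = "pac_ranking"
  )
}

#' @export
print.pac_ranking <- function(x, ...) {
  cat("Ranking consistency for ", x$gas, " (k = ", x$k, ", ", x$n_days,
      " days)\n", sep = "")
  pa <- x$per_animal
  lo <- pa[order(-pa$days_bottom_k), ][1:3, ]
  hi <- pa[order(-pa$days_top_k), ][1:3, ]
  cat("most persistent low emitters:",
      paste0(lo$animal_id, " (", lo$pct_bottom_k, "%)", collapse = ", "), "\n")
  cat("most persistent high emitters:",
      paste0(hi$animal_id, " (", hi$pct_top_k, "%)", collapse = ", "), "\n")
  if (length(x$tied_days)) {
    cat("ties at the k-th boundary on days:",
        paste(x$tied_days, collapse = ", "), "\n")
  }
  invisible(x)
}
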