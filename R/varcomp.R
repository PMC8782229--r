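#' Model specification for variance-component fits
#'
#' @param gas One of `"CH4"`, `"O2"`, `"CO2"`.
#' @param fixed Character vector of fixed-effect covariates, a subset of
#'   `c("liveweight", "humidity")`; the intercept is always included.
#'   `character(0)` gives the intercept-only model used for the raw
#'   variance decomposition.
#' @param random Character vector of random effects, a subset of
#'   `c("animal", "day")`. May be empty only inside nested-model likelihood
#'   comparisons ([lrt_nested()]); variance estimation requires at least
#'   one random effect.
#'
#' @return An object of class `pac_modelspec`.
#' @export
model_spec <- function(gas, fixed = character(), random = c("animal", "day")) {
  gas <- match.arg(gas, pac_gases())
  fixed <- as.character(fixed)
  random <- as.character(random)
  stopifnot(all(fixed %in% c("liveweight", "humidity")),
            all(random %in% c("animal", "day")))
  structure(list(gas = gas, fixed = fixed, random = random),
            class = "pac_modelspec")
}

# covariate column per fixed-effect name
.fixed_cols <- c(liveweight = "liveweight_kg", humidity = "humidity_pct")

# response/design extraction for one gas
.model_data <- function(flux_tab, spec) {
  d <- flux_tab[flux_tab$gas == spec$gas, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for gas ", spec$gas)
  need <- unname(.fixed_cols[spec$fixed])
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("flux table lacks covariates: ",
                         paste(miss, collapse = ", "))
  d$day_f <- factor(d$day_index)
  d$animal_f <- factor(d$animal_id)
  d
}

.fixed_formula_rhs <- function(spec) {
  if (length(spec$fixed) == 0L) "1"
  else paste(c("1", unname(.fixed_cols[spec$fixed])), collapse = " + ")
}

#' Restricted log-likelihood of the crossed random-effects model
#'
#' Direct dense evaluation of the restricted (REML) log-likelihood of
#' `y = X beta + Z_a a + Z_d d + e` at a given variance triple:
#' `lR = -1/2 [ log|V| + log|X' V^-1 X| + r' V^-1 r + (n - p) log 2pi ]`
#' with `V = s2_animal Za Za' + s2_day Zd Zd' + s2_error I` and `r` the
#' GLS residual. Written independently of the REML fitter so it can serve
#' as a cross-check of fitted log-likelihoods and as the objective whose
#' curvature yields variance-component standard errors.
#'
#' @param sigma2 Numeric triple `(animal, day, error)`; components whose
#'   design matrix is absent are ignored.
#' @param y Response vector.
#' @param X Fixed-effects design matrix (full column rank).
#' @param Za,Zd Random-effect indicator matrices (or `NULL` to omit the
#'   component).
#' @return The restricted log-likelihood (scalar), `-Inf` if `V` is not
#'   positive definite.
#' @export
reml_loglik <- function(sigma2, y, X, Za = NULL, Zd = NULL) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(sigma2[3], n)
  if (!is.null(Za)) V <- V + sigma2[1] * tcrossprod(Za)
  if (!is.null(Zd)) V <- V + sigma2[2] * tcrossprod(Zd)
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(-Inf)
  logdetV <- 2 * sum(log(diag(cV)))
  Vi_yX <- backsolve(cV, forwardsolve(t(cV), cbind(y, X)))
  Vi_y <- Vi_yX[, 1]
  Vi_X <- Vi_yX[, -1, drop = FALSE]
  XtViX <- crossprod(X, Vi_X)
  cXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXtViX)) return(-Inf)
  logdetXVX <- 2 * sum(log(diag(cXtViX)))
  beta <- backsolve(cXtViX, forwardsolve(t(cXtViX), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- Vi_y - Vi_X %*% beta
  quad <- drop(crossprod(r, Vi_r))
  -0.5 * (logdetV + logdetXVX + quad + (n - p) * log(2 * pi))
}

# Fast restricted log-likelihood via Henderson's mixed-model equations:
# log|V| + log|X'V^-1 X| = log|R| + log|G| + log|C| with C the MME
# coefficient matrix, and y'Py from its solution. Crossproducts are
# precomputed once, so each evaluation costs O((p + a + b)^3) instead of
# O(n^3); equality with the direct dense reml_loglik() is checked in the
# test suite. Requires every present variance to be strictly positive.
.reml_mme_factory <- function(y, X, Za = NULL, Zd = NULL) {
  W <- cbind(X, Za, Zd)
  WtW <- crossprod(W)
  Wty <- drop(crossprod(W, y))
  yty <- sum(y^2)
  n <- length(y)
  p <- ncol(X)
  ia <- if (!is.null(Za)) p + seq_len(ncol(Za)) else integer()
  id <- if (!is.null(Zd)) p + length(ia) + seq_len(ncol(Zd)) else integer()
  function(sigma2) {
    s2a <- sigma2[1]; s2d <- sigma2[2]; s2e <- sigma2[3]
    if (s2e <= 0 || (length(ia) && s2a <= 0) || (length(id) && s2d <= 0)) {
      return(-Inf)
    }
    C <- WtW / s2e
    if (length(ia)) diag(C)[ia] <- diag(C)[ia] + 1 / s2a
    if (length(id)) diag(C)[id] <- diag(C)[id] + 1 / s2d
    cC <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(cC)) return(-Inf)
    rhs <- Wty / s2e
    theta <- backsolve(cC, forwardsolve(t(cC), rhs))
    quad <- yty / s2e - sum(rhs * theta)
    ldG <- (if (length(ia)) length(ia) * log(s2a) else 0) +
      (if (length(id)) length(id) * log(s2d) else 0)
    -0.5 * ((n - p) * log(2 * pi) + n * log(s2e) + ldG +
              2 * sum(log(diag(cC))) + quad)
  }
}

# shared constructor for fitted variance-component objects
.new_varcomp <- function(sigma2, se, mu, logLik, estimator, spec,
                         n_animals, n_days, n_obs, truncated) {
  structure(
    list(sigma2 = sigma2, se = se, mu = mu,
         H_ani = NA_real_, CV = NA_real_, repeatability = NA_real_,
         logLik = logLik, estimator = estimator, spec = spec,
         n_animals = n_animals, n_days = n_days, n_obs = n_obs,
         truncated = truncated),
    class = "pac_varcomp"
  )
}

#' Construct a variance-component object from known values
#'
#' Wraps externally obtained variance components (for example a published
#' variance-component table) in the same container returned by the fitters,
#' with derived summaries filled in, so that downstream precision and
#' reporting functions can be applied to them.
#'
#' @param animal,day,error Variance components, (l/h)^2.
#' @param mu Trait mean, l/h.
#' @param gas Gas label.
#' @param ... Passed to [derive_summaries()].
#' @return A `pac_varcomp` with estimator `"given"`.
#' @export
variance_components <- function(animal, day, error, mu, gas = "CH4", ...) {
  stopifnot(animal >= 0, day >= 0, error >= 0)
  vc <- .new_varcomp(
    sigma2 = c(animal = animal, day = day, error = error),
    se = c(animal = NA_real_, day = NA_real_, error = NA_real_),
    mu = mu, logLik = NA_real_, estimator = "given",
    spec = model_spec(gas), n_animals = NA_integer_, n_days = NA_integer_,
    n_obs = NA_integer_, truncated = character()
  )
  derive_summaries(vc, ...)
}

#' Balanced-ANOVA variance components (closed form)
#'
#' Method-of-moments estimator for the two-way crossed random-effects model
#' with one observation per animal-day cell, from the expected mean squares:
#' `s2_error = MS_error`, `s2_animal = (MS_animal - MS_error) / n_days`,
#' `s2_day = (MS_day - MS_error) / n_animals`. Negative solutions are
#' truncated to zero and flagged. Requires a complete balanced layout;
#' unbalanced data must go through [fit_reml()]. On balanced data with all
#' estimates interior this closed form coincides with REML, which is why it
#' serves as the package's independent oracle for the iterative fitter.
#'
#' Standard errors use the large-sample chi-square approximation
#' `Var(MS) ~ 2 MS^2 / df` with independence of the mean squares.
#'
#' @param flux_tab Flux table from [flux_table()] (or any data frame with
#'   `animal_id`, `day_index`, `gas`, `flux_lph`).
#' @param gas Gas to analyse.
#' @return A `pac_varcomp` with intercept-only model summaries filled in.
#' @export
fit_anova_balanced <- function(flux_tab, gas) {
  spec <- model_spec(gas)
  d <- .model_data(flux_tab, spec)
  tab <- table(d$animal_f, d$day_f)
  if (any(tab != 1L)) {
    stop("layout is not balanced/complete (one record per animal-day); ",
         "use fit_reml() for unbalanced data")
  }
  y <- d$flux_lph
  a <- nlevels(d$animal_f)
  b <- nlevels(d$day_f)
  if (a < 2L || b < 2L) stop("need at least 2 animals and 2 days")
  mu <- mean(y)
  ybar_i <- tapply(y, d$animal_f, mean)
  ybar_j <- tapply(y, d$day_f, mean)
  msa <- b * sum((ybar_i - mu)^2) / (a - 1)
  msb <- a * sum((ybar_j - mu)^2) / (b - 1)
  fitted_add <- ybar_i[as.integer(d$animal_f)] + ybar_j[as.integer(d$day_f)] - mu
  mse <- sum((y - fitted_add)^2) / ((a - 1) * (b - 1))
  raw <- c(animal = (msa - mse) / b, day = (msb - mse) / a, error = mse)
  sigma2 <- pmax(raw, 0)
  truncated <- names(raw)[raw < 0]
  se <- c(
    animal = sqrt((2 * msa^2 / (a - 1) + 2 * mse^2 / ((a - 1) * (b - 1))) / b^2),
    day = sqrt((2 * msb^2 / (b - 1) + 2 * mse^2 / ((a - 1) * (b - 1))) / a^2),
    error = sqrt(2 * mse^2 / ((a - 1) * (b - 1)))
  )
  ll <- if (sigma2["error"] > 0) {
    X <- matrix(1, length(y), 1)
    Za <- stats::model.matrix(~ 0 + animal_f, d)
    Zd <- stats::model.matrix(~ 0 + day_f, d)
    reml_loglik(unname(sigma2), y, X, Za, Zd)
  } else {
    NA_real_
  }
  vc <- .new_varcomp(sigma2, se, mu, ll, "anova", spec, a, b, length(y),
                     truncated)
  derive_summaries(vc)
}

#' REML variance components for the crossed animal x day model
#'
#' Fits `flux ~ fixed effects + (1 | animal) [+ (1 | day)]` by restricted
#' maximum likelihood (via \pkg{lme4}) and returns the variance triple,
#' the restricted log-likelihood (re-evaluated with [reml_loglik()] so
#' that nested fits are compared on one fixed convention), and
#' observed-information standard errors obtained from the numeric Hessian
#' of the restricted log-likelihood at the optimum. Handles missing
#' animal-day cells. Components estimated on the zero boundary are flagged
#' and their standard errors reported as `NA` (the quadratic approximation
#' is invalid there).
#'
#' @param flux_tab Flux table (see [flux_table()]).
#' @param spec A `pac_modelspec`; its `random` set must be non-empty.
#' @param se Compute standard errors (skip in large simulation loops).
#' @return A `pac_varcomp` with summaries filled in via
#'   [derive_summaries()].
#' @export
fit_reml <- function(flux_tab, spec, se = TRUE) {
  stopifnot(inherits(spec, "pac_modelspec"))
  d <- .model_data(flux_tab, spec)
  if (nlevels(d$animal_f) < 2L || nlevels(d$day_f) < 2L) {
    stop("need at least 2 animals and 2 days")
  }
  X <- stats::model.matrix(
    stats::as.formula(paste("~", .fixed_formula_rhs(spec))), d)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  fit <- .fit_lmm(d, spec)
  sigma2 <- fit$sigma2
  Za <- if ("animal" %in% spec$random) {
    stats::model.matrix(~ 0 + animal_f, d)
  }
  Zd <- if ("day" %in% spec$random) stats::model.matrix(~ 0 + day_f, d)
  llfun <- .reml_mme_factory(d$flux_lph, X, Za, Zd)
  boundary_tol <- 1e-8 * max(sigma2["error"], sum(sigma2))
  interior <- c(sigma2[1] > boundary_tol | !("animal" %in% spec$random),
                sigma2[2] > boundary_tol | !("day" %in% spec$random),
                TRUE)
  if (all(interior)) {
    # polish the estimates on the restricted log-likelihood (log scale,
    # so positivity is automatic) until the optimum is tight
    free <- c("animal" %in% spec$random, "day" %in% spec$random, TRUE)
    nll <- function(lpar) {
      s2 <- sigma2
      s2[free] <- exp(lpar)
      -llfun(s2)
    }
    opt <- tryCatch(
      stats::optim(log(sigma2[free]), nll, method = "BFGS",
                   control = list(reltol = 1e-15, maxit = 200)),
      error = function(e) NULL
    )
    if (!is.null(opt) && is.finite(opt$value) &&
        -opt$value >= llfun(sigma2) - 1e-8) {
      sigma2[free] <- exp(opt$par)
    }
    # Newton refinement to drive the restricted-likelihood gradient to
    # zero (quadratic convergence near the optimum)
    lp <- log(sigma2[free])
    for (it in 1:10) {
      g <- tryCatch(pracma::grad(function(x) -nll(x), lp),
                    error = function(e) NULL)
      if (is.null(g) || !all(is.finite(g))) break
      if (max(abs(g)) < 1e-9) break
      H <- tryCatch(pracma::hessian(function(x) -nll(x), lp),
                    error = function(e) NULL)
      if (is.null(H) || !all(is.finite(H))) break
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      cand <- lp - step
      if (!is.finite(nll(cand)) || nll(cand) > nll(lp) + 1e-10) break
      if (max(abs(cand - lp)) < 1e-12) {
        lp <- cand
        break
      }
      lp <- cand
    }
    if (-nll(lp) >= llfun(sigma2) - 1e-10) sigma2[free] <- exp(lp)
  }
  ll <- llfun(unname(sigma2))
  truncated <- names(sigma2)[c(sigma2[1] <= boundary_tol & "animal" %in% spec$random,
                               sigma2[2] <= boundary_tol & "day" %in% spec$random,
                               FALSE)]
  ses <- c(animal = NA_real_, day = NA_real_, error = NA_real_)
  if (se) {
    free <- c("animal" %in% spec$random & !("animal" %in% truncated),
              "day" %in% spec$random & !("day" %in% truncated),
              TRUE)
    est <- sigma2[free]
    # Hessian in relative coordinates (multiples of the estimates) so the
    # finite-difference steps respect the scale of each component
    obj <- function(th) {
      s2 <- sigma2
      s2[free] <- th * est
      llfun(s2)
    }
    H <- tryCatch(pracma::hessian(obj, rep(1, sum(free))),
                  error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H))) {
      cov_rel <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(cov_rel) && isTRUE(all(diag(cov_rel) > 0))) {
        ses[free] <- est * sqrt(diag(cov_rel))
      }
    }
  }
  vc <- .new_varcomp(sigma2, ses, mean(d$flux_lph), ll, "reml", spec,
                     nlevels(d$animal_f), nlevels(d$day_f), nrow(d),
                     truncated)
  derive_summaries(vc)
}

# lme4 backend; returns the variance triple (absent random effects -> 0)
.fit_lmm <- function(d, spec) {
  re_terms <- c(
    if ("animal" %in% spec$random) "(1 | animal_f)",
    if ("day" %in% spec$random) "(1 | day_f)"
  )
  if (length(re_terms) == 0L) {
    # pure fixed-effects model: REML residual variance from least squares
    form <- stats::as.formula(paste("flux_lph ~", .fixed_formula_rhs(spec)))
    lmfit <- stats::lm(form, data = d)
    s2e <- sum(stats::residuals(lmfit)^2) / stats::df.residual(lmfit)
    return(list(sigma2 = c(animal = 0, day = 0, error = s2e), fit = lmfit))
  }
  form <- stats::as.formula(paste(
    "flux_lph ~", .fixed_formula_rhs(spec), "+",
    paste(re_terms, collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  list(
    sigma2 = c(animal = get_vc("animal_f"), day = get_vc("day_f"),
               error = get_vc("Residual")),
    fit = fit
  )
}

#' Derived variance-share summaries
#'
#' Fills the animal variance share
#' `H_ani = s2_animal / (s2_animal + s2_day + s2_error)`, the
#' between-animal coefficient of variation `CV = sqrt(s2_animal) / mu`,
#' and the repeatability. Repeatability defaults to the intra-animal
#' correlation `s2_animal / (s2_animal + s2_error)` (day effects, common
#' to all animals measured that day, treated as a measurement-occasion
#' shift); set `repeatability_denominator = "total"` to include the day
#' variance in the denominator.
#'
#' @param vc A `pac_varcomp`.
#' @param repeatability_denominator `"animal_error"` (default) or
#'   `"total"`.
#' @return The `pac_varcomp` with `H_ani`, `CV`, `repeatability` filled.
#' @export
derive_summaries <- function(vc,
                             repeatability_denominator = c("animal_error",
                                                           "total")) {
  stopifnot(inherits(vc, "pac_varcomp"))
  repeatability_denominator <- match.arg(repeatability_denominator)
  s <- vc$sigma2
  total <- sum(s)
  vc$H_ani <- if (total > 0) unname(s["animal"] / total) else 0
  if (vc$mu == 0) stop("CV undefined: trait mean is zero")
  vc$CV <- unname(sqrt(s["animal"]) / vc$mu)
  denom <- if (repeatability_denominator == "total") total
           else unname(s["animal"] + s["error"])
  vc$repeatability <- if (denom > 0) unname(s["animal"] / denom) else 0
  vc
}

#' @export
print.pac_varcomp <- function(x, digits = 4, ...) {
  cat("Variance components (", x$estimator, ") for ", x$spec$gas, ", ",
      x$n_obs, " records (", x$n_animals, " animals x ", x$n_days,
      " days)\n", sep = "")
  m <- rbind(estimate = x$sigma2, se = x$se)
  print(signif(m, digits))
  cat("mean ", signif(x$mu, digits),
      " l/h | H_ani ", signif(100 * x$H_ani, digits),
      "% | CV ", signif(x$CV, digits),
      " | repeatability ", signif(x$repeatability, digits),
      " | logLik ", signif(x$logLik, 8), "\n", sep = "")
  if (length(x$truncated)) {
    cat("components truncated at zero:", paste(x$truncated, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Repeatability over a prefix window of consecutive days
#'
#' Re-fits the repeatability model on the records of days `1..n` and
#' returns the repeatability, mirroring how precision of consecutive-day
#' protocols is assessed. The default model uses liveweight and humidity
#' as fixed effects with animal and day random.
#'
#' @param flux_tab Flux table.
#' @param gas Gas to analyse.
#' @param n Number of consecutive days from day 1 (2 <= n <= days present).
#' @param spec Optional `pac_modelspec` override.
#' @param ... Passed to [fit_reml()].
#' @return Repeatability (scalar proportion).
#' @export
repeatability_by_window <- function(flux_tab, gas, n, spec = NULL, ...) {
  days <- sort(unique(flux_tab$day_index))
  if (n < 2L || n > length(days)) {
    stop("n must be between 2 and the number of days present (",
         length(days), ")")
  }
  if (is.null(spec)) spec <- model_spec(gas, fixed = c("liveweight", "humidity"))
  sub <- flux_tab[flux_tab$day_index %in% days[seq_len(n)], , drop = FALSE]
  fit_reml(sub, spec, ...)$repeatability
}

#' Likelihood-ratio test for nested random-effects structures
#'
#' Compares two REML fits sharing the same fixed effects, where the reduced
#' model's random effects are a subset of the full model's. The statistic
#' is `2 (logLik_full - logLik_reduced)` (restricted log-likelihoods,
#' comparable because the fixed-effects design is identical). Because the
#' dropped variances lie on the boundary of the parameter space under the
#' null, the p-value uses the chi-square boundary mixture:
#' `0.5 chi2_0 + 0.5 chi2_1` when one variance is dropped, and
#' `0.25 chi2_0 + 0.5 chi2_1 + 0.25 chi2_2` when both are dropped.
#'
#' @param full_spec,reduced_spec `pac_modelspec` objects with identical
#'   fixed effects and nested random sets.
#' @param flux_tab Flux table.
#' @return List with `statistic`, `df_dropped`, `p_value`, the two
#'   restricted log-likelihoods, and both fits.
#' @export
lrt_nested <- function(full_spec, reduced_spec, flux_tab) {
  stopifnot(inherits(full_spec, "pac_modelspec"),
            inherits(reduced_spec, "pac_modelspec"))
  if (!identical(sort(full_spec$fixed), sort(reduced_spec$fixed)) ||
      !identical(full_spec$gas, reduced_spec$gas)) {
    stop("specs must share gas and fixed effects")
  }
  if (!all(reduced_spec$random %in% full_spec$random)) {
    stop("reduced model's random effects are not nested in the full model's")
  }
  fit_full <- fit_reml(flux_tab, full_spec, se = FALSE)
  fit_red <- if (length(reduced_spec$random) == 0L) {
    d <- .model_data(flux_tab, reduced_spec)
    X <- stats::model.matrix(
      stats::as.formula(paste("~", .fixed_formula_rhs(reduced_spec))), d)
    lmm <- .fit_lmm(d, reduced_spec)
    ll <- reml_loglik(unname(lmm$sigma2), d$flux_lph, X, NULL, NULL)
    vc <- .new_varcomp(lmm$sigma2, c(animal = NA, day = NA, error = NA),
                       mean(d$flux_lph), ll, "reml", reduced_spec,
                       nlevels(d$animal_f), nlevels(d$day_f), nrow(d),
                       character())
    derive_summaries(vc)
  } else {
    fit_reml(flux_tab, reduced_spec, se = FALSE)
  }
  k <- length(setdiff(full_spec$random, reduced_spec$random))
  stat <- 2 * (fit_full$logLik - fit_red$logLik)
  stat <- max(stat, 0)
  p <- if (stat <= 1e-12) {
    1
  } else if (k == 0L) {
    1
  } else if (k == 1L) {
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) +
      0.25 * stats::pchisq(stat, df = 2, lower.tail = FALSE)
  }
  list(statistic = stat, df_dropped = k, p_value = p,
       logLik_full = fit_full$logLik, logLik_reduced = fit_red$logLik,
       fit_full = fit_full, fit_reduced = fit_red)
}
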