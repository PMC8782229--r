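#' Specification of the gaseous-output prediction model
#'
#' The prediction equation regresses a gas flux (l/h) on measurement date
#' (class), measurement group/run (class), breed (class), age, liveweight,
#' relative humidity, temperature and pressure (covariates), with a random
#' animal intercept, and is evaluated by stratified k-fold
#' cross-validation.
#'
#' @param gas Response gas.
#' @param n_folds Number of cross-validation folds (default 4).
#' @param seed Seed for the fold assignment.
#' @return An object of class `pac_predspec`.
#' @export
prediction_spec <- function(gas, n_folds = 4L, seed = 1L) {
  gas <- match.arg(gas, pac_gases())
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 2L)
  structure(list(gas = gas, n_folds = n_folds, seed = as.integer(seed)),
            class = "pac_predspec")
}

#' Stratified fold assignment
#'
#' Allocates records to `n_folds` folds of as equal size as possible
#' (sizes differ by at most one), stratified by animal and date: each
#' animal's records, taken in date order, are spread across folds via a
#' seeded random assignment, and the remainder records are placed in the
#' currently smallest folds so the global balance is kept. Deterministic
#' given the seed.
#'
#' @param data Data frame with `animal_id` and `day_index`.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..n_folds), one per row of `data`.
#' @export
make_folds <- function(data, n_folds = 4L, seed = 1L) {
  n <- nrow(data)
  n_folds <- as.integer(n_folds)
  if (n < n_folds) stop("fewer records (", n, ") than folds (", n_folds, ")")
  set.seed(as.integer(seed))
  fold <- integer(n)
  sizes <- integer(n_folds)
  for (a in sort(unique(data$animal_id))) {
    idx <- which(data$animal_id == a)
    idx <- idx[order(data$day_index[idx])]
    ni <- length(idx)
    base <- ni %/% n_folds
    rem <- ni %% n_folds
    counts <- rep(base, n_folds)
    if (rem > 0L) {
      # remainder records go to the smallest folds, random tie-break
      pick <- order(sizes + stats::runif(n_folds))[seq_len(rem)]
      counts[pick] <- counts[pick] + 1L
    }
    labels <- sample(rep.int(seq_len(n_folds), counts))
    fold[idx] <- labels
    sizes <- sizes + counts
  }
  fold
}

# prediction-model formula terms; class terms with < 2 levels in the
# training data are dropped to keep the design full rank
.pred_formula <- function(train) {
  class_terms <- c(date_f = "date_f", group_f = "group_f", breed_f = "breed_f")
  keep_class <- names(class_terms)[vapply(class_terms, function(v)
    nlevels(train[[v]]) >= 2L, logical(1))]
  covars <- c("age_months", "liveweight_kg", "humidity_pct", "temp_c",
              "pressure_hpa")
  keep_cov <- covars[vapply(covars, function(v)
    stats::sd(train[[v]]) > 0, logical(1))]
  rhs <- paste(c("1", keep_class, keep_cov), collapse = " + ")
  stats::as.formula(paste("flux_lph ~", rhs, "+ (1 | animal_f)"))
}

.pred_factors <- function(d) {
  d$date_f <- factor(d$day_index)
  d$group_f <- factor(d$run_index)
  d$breed_f <- factor(d$breed)
  d$animal_f <- factor(d$animal_id)
  d
}

#' Fit the prediction model on training records and predict held-out ones
#'
#' Fits the mixed model of [prediction_spec()] by REML on the training
#' records and predicts the held-out records as fixed-effect part plus the
#' animal's predicted random effect (BLUP) when the animal was observed in
#' training, or the fixed-effect part alone otherwise. Held-out records
#' carrying a class level unseen in training are predicted with that
#' effect at the reference level and flagged.
#'
#' @param train,test Flux-table rows (one gas) with the prediction
#'   covariates.
#' @param spec A `pac_predspec`.
#' @return Data frame: `animal_id`, `day_index`, `actual`, `predicted`,
#'   `new_animal`, `new_level` flags.
#' @export
fit_and_predict <- function(train, test, spec) {
  stopifnot(inherits(spec, "pac_predspec"))
  train <- .pred_factors(train[train$gas == spec$gas, , drop = FALSE])
  test <- .pred_factors(test[test$gas == spec$gas, , drop = FALSE])
  if (nrow(train) == 0L || nrow(test) == 0L) stop("empty train or test set")
  form <- .pred_formula(train)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = train, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )
  # map unseen class levels to the training reference level, flagged
  new_level <- rep(FALSE, nrow(test))
  for (v in c("date_f", "group_f", "breed_f")) {
    tl <- levels(train[[v]])
    unseen <- !(as.character(test[[v]]) %in% tl)
    new_level <- new_level | unseen
    x <- as.character(test[[v]])
    x[unseen] <- tl[1]
    test[[v]] <- factor(x, levels = tl)
  }
  new_animal <- !(as.character(test$animal_f) %in% levels(train$animal_f))
  if (!is.null(fit)) {
    pred <- stats::predict(fit, newdata = test, allow.new.levels = TRUE)
  } else {
    # degenerate training response (e.g. zero residual variance): fit the
    # animal effect as fixed, the no-shrinkage limit of the mixed model
    form_lm <- stats::update(stats::as.formula(lme4::nobars(form)),
                             . ~ . + animal_f)
    lmfit <- suppressWarnings(stats::lm(form_lm, data = train,
                                        singular.ok = TRUE))
    test_lm <- test
    al <- levels(train$animal_f)
    x <- as.character(test_lm$animal_f)
    x[new_animal] <- al[1]
    test_lm$animal_f <- factor(x, levels = al)
    pred <- suppressWarnings(stats::predict(lmfit, newdata = test_lm))
  }
  data.frame(
    animal_id = test$animal_id,
    day_index = test$day_index,
    actual = test$flux_lph,
    predicted = as.numeric(pred),
    new_animal = new_animal,
    new_level = new_level,
    stringsAsFactors = FALSE
  )
}

#' Cross-validate the prediction equation
#'
#' Runs [make_folds()] and [fit_and_predict()] over all folds, holding out
#' one fold at a time, and summarises per-fold and averaged goodness of
#' fit: `r2` (squared Pearson correlation of predicted vs actual on the
#' held-out records), `RMSE` (l/h), predicted and actual means and the
#' mean bias (predicted - actual). The pooled `r2` over all held-out
#' records is reported alongside the fold average.
#'
#' @param data Flux table (all gases fine; the spec's gas is selected).
#' @param spec A `pac_predspec`.
#' @return An object of class `pac_cv`: list with `per_fold`, `summary`,
#'   record-level `predictions`, and the spec.
#' @export
cross_validate <- function(data, spec) {
  stopifnot(inherits(spec, "pac_predspec"))
  d <- data[data$gas == spec$gas, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for gas ", spec$gas)
  fold <- make_folds(d, spec$n_folds, spec$seed)
  preds <- vector("list", spec$n_folds)
  for (f in seq_len(spec$n_folds)) {
    preds[[f]] <- cbind(
      fold = f,
      fit_and_predict(d[fold != f, , drop = FALSE],
                      d[fold == f, , drop = FALSE], spec)
    )
  }
  all_pred <- do.call(rbind, preds)
  fold_stats <- do.call(rbind, lapply(preds, function(p) {
    r2 <- if (stats::sd(p$actual) > 0 && stats::sd(p$predicted) > 0) {
      stats::cor(p$actual, p$predicted)^2
    } else {
      NA_real_
    }
    data.frame(
      fold = p$fold[1],
      n = nrow(p),
      r2 = r2,
      rmse = sqrt(mean((p$predicted - p$actual)^2)),
      predicted_mean = mean(p$predicted),
      actual_mean = mean(p$actual)
    )
  }))
  pooled_r2 <- if (stats::sd(all_pred$actual) > 0 &&
                   stats::sd(all_pred$predicted) > 0) {
    stats::cor(all_pred$actual, all_pred$predicted)^2
  } else {
    NA_real_
  }
  summary <- data.frame(
    gas = spec$gas,
    n_folds = spec$n_folds,
    r2_mean = mean(fold_stats$r2),
    r2_pooled = pooled_r2,
    rmse_mean = mean(fold_stats$rmse),
    rmse_pooled = sqrt(mean((all_pred$predicted - all_pred$actual)^2)),
    predicted_mean = mean(fold_stats$predicted_mean),
    actual_mean = mean(fold_stats$actual_mean),
    mean_bias = mean(fold_stats$predicted_mean - fold_stats$actual_mean)
  )
  structure(
    list(per_fold = fold_stats, summary = summary, predictions = all_pred,
         spec = spec),
    class = "pac_cv"
  )
}

#' @export
print.pac_cv <- function(x, digits = 3, ...) {
  s <- x$summary
  cat("Cross-validated prediction of ", s$gas, " flux (", s$n_folds,
      " folds)\n", sep = "")
  cat("  r2 (fold mean) ", signif(s$r2_mean, digits),
      " | r2 (pooled) ", signif(s$r2_pooled, digits),
      " | RMSE ", signif(s$rmse_mean, digits), " l/h\n", sep = "")
  cat("  predicted mean ", signif(s$predicted_mean, digits),
      " vs actual ", signif(s$actual_mean, digits),
      " l/h (bias ", signif(s$mean_bias, digits), ")\n", sep = "")
  invisible(x)
}
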