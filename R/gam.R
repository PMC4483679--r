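indicator_column <- function(indicator) {
  switch(indicator,
         mean = "tmean", max = "tmax", min = "tmin",
         tmean = "tmean", tmax = "tmax", tmin = "tmin",
         stop_tm("unknown temperature indicator '%s'", indicator,
                 class = "tempmort_config_error"))
}

#' Cold/heat reference thresholds of a region's temperature distribution
#'
#' The 10th percentile of the daily temperature indicator is the cold
#' reference and the 90th percentile the heat reference, computed with the
#' linear-interpolation convention ([stats::quantile()] type 7; the `type`
#' argument substitutes another convention).
#'
#' @param series Daily region series with the indicator column present.
#' @param p_low,p_high Reference percentiles.
#' @param indicator `"mean"`, `"max"` or `"min"` daily temperature.
#' @param type Quantile algorithm.
#' @param min_days Minimum required non-missing days.
#' @return A `tm_thresholds` list: `tau_low`, `tau_high`, `indicator`.
#' @export
temperature_thresholds <- function(series, p_low = 10, p_high = 90,
                                   indicator = "mean", type = 7,
                                   min_days = 100L) {
  x <- series[[indicator_column(indicator)]]
  x <- x[!is.na(x)]
  if (length(x) < min_days)
    stop_tm("need >= %d non-missing temperature days, have %d", min_days,
            length(x), class = "tempmort_insufficient_data")
  tau_low <- percentile(x, p_low, type)
  tau_high <- percentile(x, p_high, type)
  stopifnot(tau_low <= tau_high)
  structure(list(tau_low = tau_low, tau_high = tau_high,
                 indicator = indicator), class = "tm_thresholds")
}

#' Stratified lag-window means of the temperature indicator
#'
#' For day `t`, `T_1_3` is the mean of the indicator on days `t-1 .. t-3`,
#' `T_4_8` over `t-4 .. t-8` and `T_9_14` over `t-9 .. t-14`. The first 14
#' days lack full history and are returned as `NA`; they are excluded from
#' the analysis set downstream.
#'
#' @param series Daily region series (contiguous dates).
#' @param indicator Temperature indicator.
#' @return Data frame `date, T_1_3, T_4_8, T_9_14`, aligned with `series`.
#' @export
build_lag_features <- function(series, indicator = "mean") {
  series <- series[order(as.Date(series$date)), ]
  gaps <- date_gaps(series$date)
  if (length(gaps))
    stop_tm("date gap(s): %s", paste(gaps, collapse = ", "),
            class = "tempmort_date_gap")
  x <- series[[indicator_column(indicator)]]
  n <- length(x)
  win_mean <- function(from, to) {  # lags from..to (from < to)
    out <- rep(NA_real_, n)
    if (n > to)
      for (t in (to + 1L):n) out[t] <- mean(x[(t - to):(t - from)])
    out
  }
  data.frame(date = as.Date(series$date),
             T_1_3 = win_mean(1L, 3L),
             T_4_8 = win_mean(4L, 8L),
             T_9_14 = win_mean(9L, 14L))
}

#' Natural cubic regression-spline basis with fixed df
#'
#' A natural cubic spline basis ([splines::ns]) with `df` columns and
#' interior knots at equally spaced quantiles of `x`, centered so the block
#' is identifiable alongside an intercept. Linear functions of `x` lie in
#' the span of the basis plus intercept, and a df basis is nested in any
#' higher-df basis in fitting power.
#'
#' @param x Covariate values.
#' @param df Number of basis columns (>= 2).
#' @param name Column-name prefix.
#' @return A `tm_spline_basis`: `basis` (n x df matrix), `knots`,
#'   `boundary`, `centers`, `df`.
#' @export
spline_basis <- function(x, df, name = "s") {
  if (df < 2) stop_tm("df must be >= 2", class = "tempmort_config_error")
  if (length(unique(x)) < df)
    stop_tm("only %d distinct values for a df=%d basis",
            length(unique(x)), df, class = "tempmort_rank_error")
  b <- splines::ns(x, df = df)
  centers <- colMeans(b)
  m <- sweep(unclass(b), 2L, centers)
  colnames(m) <- paste0(name, seq_len(df))
  structure(list(basis = m, knots = attr(b, "knots"),
                 boundary = attr(b, "Boundary.knots"),
                 centers = centers, df = df, name = name),
            class = "tm_spline_basis")
}

# time-spline df: 7 per year, rounded, never below 4
time_spline_df <- function(n_days) max(4L, as.integer(round(7 * n_days / 365.25)))

dow_factor <- function(dates) {
  lev <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  factor(lev[as.integer(format(as.Date(dates), "%u"))], levels = lev)
}

#' Assemble the regression design for one region and side
#'
#' Columns: intercept; hinge temperature terms (cold:
#' `max(tau_low - T, 0)` on the three lag strata; heat:
#' `max(T - tau_high, 0)` on the 1--3 day stratum); a df-3 humidity spline
#' block; a calendar-time spline block with 7 df per year of the full
#' series (rounded, minimum 4); and 6 day-of-week dummies (Monday
#' reference). Days with incomplete 14-day lag history or missing weather
#' are dropped (complete case).
#'
#' @param series Daily region series with `deaths`, the indicator and `rh`.
#' @param thresholds A [temperature_thresholds()] result (computed from
#'   `series` when `NULL`).
#' @param side `"cold"` or `"heat"`.
#' @param indicator Temperature indicator.
#' @param lags Precomputed [build_lag_features()] (optional).
#' @param rh_df Humidity spline df.
#' @param check_rank Raise a collinearity error when the design is rank
#'   deficient (default). Disable to inspect a degenerate design, e.g. a
#'   side whose hinge never activates.
#' @return A `tm_design`: `X` (model matrix), `y` (counts), `rows` (indices
#'   into `series`), `hinge_cols`, `thresholds`, `time_df`.
#' @export
assemble_design <- function(series, thresholds = NULL,
                            side = c("cold", "heat"), indicator = "mean",
                            lags = NULL, rh_df = 3L, check_rank = TRUE) {
  side <- match.arg(side)
  series <- series[order(as.Date(series$date)), ]
  if (is.null(thresholds))
    thresholds <- temperature_thresholds(series, indicator = indicator)
  if (is.null(lags)) lags <- build_lag_features(series, indicator)
  keep <- stats::complete.cases(lags) & !is.na(series$rh) &
    !is.na(series$deaths)
  rows <- which(keep)
  if (length(rows) < 30L)
    stop_tm("only %d usable days after lag/missingness exclusions",
            length(rows), class = "tempmort_insufficient_data")
  lg <- lags[rows, ]
  if (side == "cold") {
    hinges <- cbind(cold_1_3 = pmax(thresholds$tau_low - lg$T_1_3, 0),
                    cold_4_8 = pmax(thresholds$tau_low - lg$T_4_8, 0),
                    cold_9_14 = pmax(thresholds$tau_low - lg$T_9_14, 0))
  } else {
    hinges <- cbind(heat_1_3 = pmax(lg$T_1_3 - thresholds$tau_high, 0))
  }
  rh_b <- spline_basis(series$rh[rows], rh_df, name = "rh_")
  tdf <- time_spline_df(nrow(series))
  time_b <- spline_basis(as.numeric(as.Date(series$date[rows])), tdf,
                         name = "time_")
  dow <- dow_factor(series$date[rows])
  dow_m <- stats::model.matrix(~dow)[, -1L, drop = FALSE]
  colnames(dow_m) <- sub("^dow", "dow_", colnames(dow_m))
  X <- cbind(`(Intercept)` = 1, hinges, rh_b$basis, time_b$basis, dow_m)
  qd <- qr(X)
  if (check_rank && qd$rank < ncol(X)) {
    dep <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    stop_tm("design is rank deficient; dependent column(s): %s",
            paste(dep, collapse = ", "), class = "tempmort_collinearity")
  }
  structure(list(X = X, y = series$deaths[rows], rows = rows,
                 hinge_cols = colnames(hinges), thresholds = thresholds,
                 side = side, indicator = indicator, time_df = tdf),
            class = "tm_design")
}

#' Fit a Poisson log-linear model by iteratively reweighted least squares
#'
#' Maximizes the Poisson log-likelihood with canonical log link. IRLS is
#' declared converged when the relative change in deviance falls below
#' `tol` (default 1e-8) within `max_iter` iterations; otherwise a
#' convergence error carrying the deviance trace is raised. The coefficient
#' covariance is the inverse Fisher information at the optimum.
#'
#' @param design A `tm_design`, or a numeric model matrix.
#' @param y Counts (required when `design` is a bare matrix).
#' @param tol Relative deviance tolerance.
#' @param max_iter Iteration cap.
#' @return A `tm_glm` with coefficients, `vcov`, `loglik`, `aic`,
#'   `deviance`, fitted values and the design metadata. Standard methods:
#'   [coef()], [vcov()], [logLik()], [AIC()], [fitted()], [residuals()],
#'   [predict()], [summary()].
#' @export
fit_poisson <- function(design, y = NULL, tol = 1e-8, max_iter = 100L) {
  if (inherits(design, "tm_design")) {
    X <- design$X
    y <- design$y
    meta <- design[c("hinge_cols", "thresholds", "side", "indicator",
                     "time_df", "rows")]
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    meta <- NULL
  }
  if (is.null(y) || any(y < 0) || any(y != round(y)))
    stop_tm("y must be non-negative integer counts",
            class = "tempmort_data_error")
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  beta[match("(Intercept)", colnames(X), nomatch = 1L)] <- log(mean(y) + 1e-8)
  dev_old <- Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(as.vector(X %*% beta), -30), 30)
    mu <- exp(eta)
    w <- mu
    z <- eta + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    if (anyNA(beta))
      stop_tm("design became rank deficient during IRLS",
              class = "tempmort_collinearity")
    eta <- as.vector(X %*% beta)
    mu <- exp(pmin(pmax(eta, -30), 30))
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    trace <- c(trace, dev)
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged) {
    cond <- structure(
      class = c("tempmort_convergence", "tempmort_error", "error", "condition"),
      list(message = sprintf(
        "IRLS did not converge in %d iterations; deviance trace: %s",
        max_iter, paste(signif(utils::tail(trace, 5), 8), collapse = ", ")),
        call = sys.call(), trace = trace))
    stop(cond)
  }
  info <- crossprod(X, X * mu)
  vc <- chol2inv(chol(info))
  dimnames(vc) <- list(colnames(X), colnames(X))
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = vc, loglik = ll, aic = -2 * ll + 2 * p,
                 deviance = dev, n_obs = n, df = p,
                 fitted.values = mu, y = y, columns = colnames(X),
                 iterations = it, meta = meta),
            class = "tm_glm")
}

#' @export
print.tm_glm <- function(x, ...) {
  cat(sprintf("Poisson log-linear fit: n = %d, %d coefficients\n",
              x$n_obs, x$df))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, deviance = %.3f (%d IRLS iter)\n",
              x$loglik, x$aic, x$deviance, x$iterations))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.tm_glm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, aic = object$aic,
                 loglik = object$loglik, n_obs = object$n_obs),
            class = "summary.tm_glm")
}

#' @export
print.summary.tm_glm <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat(sprintf("n = %d, logLik = %.3f, AIC = %.3f\n",
              x$n_obs, x$loglik, x$aic))
  invisible(x)
}

#' @export
coef.tm_glm <- function(object, ...) object$coefficients

#' @export
vcov.tm_glm <- function(object, ...) object$vcov

#' @export
logLik.tm_glm <- function(object, ...)
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")

#' @export
fitted.tm_glm <- function(object, ...) object$fitted.values

#' @export
residuals.tm_glm <- function(object,
                             type = c("deviance", "pearson", "response"),
                             ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted.values
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu),
         deviance = sign(y - mu) *
           sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))))
}

#' @export
predict.tm_glm <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- log(object$fitted.values)
  } else {
    X <- as.matrix(newdata)[, object$columns, drop = FALSE]
    eta <- as.vector(X %*% object$coefficients)
  }
  if (type == "response") exp(eta) else eta
}

#' Percent change in mortality per 1 degree C beyond threshold
#'
#' `(exp(beta) - 1) * 100`.
#'
#' @param beta_total Log-rate slope (finite).
#' @return Percent change.
#' @export
percent_change <- function(beta_total) {
  if (any(!is.finite(beta_total)))
    stop_tm("beta must be finite", class = "tempmort_domain_error")
  (exp(beta_total) - 1) * 100
}

#' Fit the per-region temperature-mortality model for one side
#'
#' Convenience wrapper: thresholds, lag strata, design and IRLS fit.
#'
#' @inheritParams assemble_design
#' @param ... Passed to [fit_poisson()].
#' @return A `tm_glm` whose `meta` records side, indicator and thresholds.
#' @export
fit_region_gam <- function(series, side = c("cold", "heat"),
                           indicator = "mean", thresholds = NULL, ...) {
  side <- match.arg(side)
  fit_poisson(assemble_design(series, thresholds, side, indicator), ...)
}

#' Choose the temperature indicator by AIC
#'
#' Fits the full model once per indicator (mean, max, min daily
#' temperature) and returns the indicator with minimal AIC; exact ties are
#' broken in the order mean, max, min.
#'
#' @param series Daily region series.
#' @param side `"cold"` or `"heat"`.
#' @return List: `indicator`, `aic` (named vector over indicators),
#'   `fits` (the three `tm_glm` objects), `fit` (the selected one).
#' @export
select_indicator_by_aic <- function(series, side = c("cold", "heat")) {
  side <- match.arg(side)
  inds <- c("mean", "max", "min")
  fits <- lapply(inds, function(ind) {
    tryCatch(fit_region_gam(series, side, indicator = ind),
             error = function(e) stop_tm(
               "fit failed for indicator '%s': %s", ind, conditionMessage(e),
               class = "tempmort_fit_error"))
  })
  names(fits) <- inds
  aics <- vapply(fits, `[[`, 0, "aic")
  best <- inds[which.min(aics)]  # first minimum: tie order mean > max > min
  list(indicator = best, aic = aics, fits = fits, fit = fits[[best]])
}

#' Estimate the cold/heat effect for one region
#'
#' The total slope is the sum of the side's hinge coefficients (a sustained
#' 1 degree C exceedance across the included lag strata); its standard
#' error comes from the coefficient covariance by the delta method (here a
#' linear combination, so exact). The percent change follows
#' [percent_change()]; a negative estimate is floored at 0 and flagged,
#' reflecting the zero-reference convention for regions where temperature
#' shows no deleterious effect.
#'
#' @param series Daily region series for one region.
#' @param side `"cold"` or `"heat"`.
#' @param indicator Temperature indicator, or `"aic"` to select by
#'   [select_indicator_by_aic()].
#' @param region_id Region label for the output row.
#' @param floor_negative Apply the zero floor (default `TRUE`).
#' @return One-row data frame: `region_id, side, indicator, tau,
#'   beta_total, se, percent_change, percent_change_raw, floored`.
#' @export
estimate_effects <- function(series, side = c("cold", "heat"),
                             indicator = "mean",
                             region_id = series$region_id[1L] %||% "region",
                             floor_negative = TRUE) {
  side <- match.arg(side)
  if (identical(indicator, "aic")) {
    sel <- select_indicator_by_aic(series, side)
    fit <- sel$fit
    indicator <- sel$indicator
  } else {
    fit <- fit_region_gam(series, side, indicator = indicator)
  }
  hc <- fit$meta$hinge_cols
  beta_total <- sum(fit$coefficients[hc])
  se <- sqrt(sum(fit$vcov[hc, hc]))
  raw <- percent_change(beta_total)
  floored <- floor_negative && raw < 0
  th <- fit$meta$thresholds
  data.frame(region_id = region_id, side = side, indicator = indicator,
             tau = if (side == "cold") th$tau_low else th$tau_high,
             beta_total = beta_total, se = se,
             percent_change = if (floored) 0 else raw,
             percent_change_raw = raw, floored = floored,
             stringsAsFactors = FALSE)
}

#' Effect table over all regions and sides
#'
#' @param series_all Region series for several regions (stacked, with
#'   `region_id`).
#' @param sides Sides to estimate.
#' @param indicator Indicator (or `"aic"`).
#' @return Data frame with one row per region and side (the effects CSV
#'   schema).
#' @export
estimate_effects_all <- function(series_all, sides = c("cold", "heat"),
                                 indicator = "mean") {
  out <- list()
  for (rid in unique(series_all$region_id)) {
    sr <- series_all[series_all$region_id == rid, ]
    for (sd in sides)
      out[[paste(rid, sd)]] <- estimate_effects(sr, sd, indicator,
                                                region_id = rid)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write the per-region effects CSV
#'
#' Schema: `region_id, side, indicator, tau, beta_total, se,
#' percent_change, percent_change_raw, floored`.
#' @param x Effects data frame.
#' @param path File path.
#' @return Data frame (reader) or `path` invisibly (writer).
#' @export
write_effects_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_effects_csv
#' @export
read_effects_csv <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)
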