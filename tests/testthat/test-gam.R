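test_that("reference thresholds follow the linear-interpolation convention", {
  s <- data.frame(date = as.Date("2008-01-01") + 0:109, tmean = 20)
  th <- temperature_thresholds(s)
  expect_equal(th$tau_low, 20)
  expect_equal(th$tau_high, 20)
  s2 <- data.frame(tmean = 1:11)
  th2 <- temperature_thresholds(s2, min_days = 10L)
  expect_equal(th2$tau_low, 2.0)
  th3 <- temperature_thresholds(s2, p_low = 0, p_high = 100, min_days = 10L)
  expect_equal(th3$tau_low, 1)
  expect_equal(th3$tau_high, 11)
  expect_error(temperature_thresholds(data.frame(tmean = 1:50)),
               class = "tempmort_insufficient_data")
})

test_that("lag-stratum windows are the documented means", {
  s <- data.frame(date = as.Date("2008-01-01") + 0:29, tmean = 1:30)
  lf <- build_lag_features(s)
  expect_equal(lf$T_1_3[15], 13)
  expect_equal(lf$T_4_8[15], 9)
  expect_equal(lf$T_9_14[15], 3.5)
  expect_true(all(is.na(lf$T_9_14[1:14])))
  const <- build_lag_features(data.frame(date = as.Date("2008-01-01") + 0:19,
                                         tmean = 7))
  expect_true(all(const$T_1_3[15:20] == 7 & const$T_4_8[15:20] == 7 &
                    const$T_9_14[15:20] == 7))
  # a 14-day series has no day with full history
  short <- build_lag_features(data.frame(date = as.Date("2008-01-01") + 0:13,
                                         tmean = 1:14))
  expect_true(all(is.na(short$T_9_14)))
  expect_error(build_lag_features(
    data.frame(date = as.Date("2008-01-01") + c(0:5, 7:20), tmean = 1)),
    class = "tempmort_date_gap")
})

test_that("spline basis has the contracted dimension and nests simpler fits", {
  x <- seq(0, 2 * pi, length.out = 1000)
  b3 <- spline_basis(x, 3)
  expect_equal(ncol(b3$basis), 3L)
  # linear functions are reproduced exactly through basis + intercept
  fit <- lm.fit(cbind(1, b3$basis), x)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  # df = 7 fits sin(x) strictly better than df = 3
  b7 <- spline_basis(x, 7)
  r3 <- max(abs(lm.fit(cbind(1, b3$basis), sin(x))$residuals))
  r7 <- max(abs(lm.fit(cbind(1, b7$basis), sin(x))$residuals))
  expect_lt(r7, r3)
  expect_error(spline_basis(rep(1:2, 5), 4), class = "tempmort_rank_error")
  expect_error(spline_basis(x, 1), class = "tempmort_config_error")
})

test_that("design matrix lays out hinge, spline, and dummy blocks", {
  w <- one_region_with_deaths(101L, n_days = 730L)
  d_cold <- assemble_design(w$series, side = "cold")
  expect_equal(d_cold$hinge_cols, c("cold_1_3", "cold_4_8", "cold_9_14"))
  expect_equal(sum(grepl("^time_", colnames(d_cold$X))), 14L)  # 7 df/year x 2
  expect_equal(sum(grepl("^dow_", colnames(d_cold$X))), 6L)
  expect_equal(sum(grepl("^rh_", colnames(d_cold$X))), 3L)
  d_heat <- assemble_design(w$series, side = "heat")
  expect_equal(d_heat$hinge_cols, "heat_1_3")
  # warm thresholds leave the cold hinge identically zero
  th <- structure(list(tau_low = min(w$series$tmean) - 5,
                       tau_high = max(w$series$tmean) + 5,
                       indicator = "mean"), class = "tm_thresholds")
  err <- expect_error(assemble_design(w$series, thresholds = th,
                                      side = "cold"),
                      class = "tempmort_collinearity")
  expect_match(conditionMessage(err), "cold_")
  d0 <- assemble_design(w$series, thresholds = th, side = "cold",
                        check_rank = FALSE)
  expect_true(all(d0$X[, d0$hinge_cols] == 0))
})

test_that("IRLS matches closed forms and a grid-search oracle", {
  f0 <- fit_poisson(matrix(1, 3, 1), c(2, 4, 6))
  expect_equal(unname(f0$coefficients), log(4), tolerance = 1e-9)
  set.seed(7)
  x <- runif(20, -1, 1)
  X <- cbind(`(Intercept)` = 1, x = x)
  y <- rpois(20, exp(0.4 + 0.8 * x))
  fit <- fit_poisson(X, y)
  # score equation at the canonical link: fitted totals match observed
  expect_lt(abs(sum(fitted(fit)) - sum(y)), 1e-6)
  # dense grid search over (a, b), refined twice around the optimum
  ll <- function(a, b) sum(dpois(y, exp(a + b * x), log = TRUE))
  ctr <- c(0, 0); span <- 3
  for (pass in 1:3) {
    g <- expand.grid(a = seq(ctr[1] - span, ctr[1] + span, length.out = 121),
                     b = seq(ctr[2] - span, ctr[2] + span, length.out = 121))
    g$ll <- mapply(ll, g$a, g$b)
    ctr <- unlist(g[which.max(g$ll), c("a", "b")])
    span <- span / 20
  }
  expect_lt(max(abs(fit$coefficients - ctr)), 1e-4)
  # AIC identity and covariance symmetry
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2)
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  expect_error(fit_poisson(X, y - 5), class = "tempmort_data_error")
})

test_that("tm_glm methods agree with the stats generics' contracts", {
  w <- one_region_with_deaths(103L)
  fit <- fit_region_gam(w$series, "heat")
  expect_s3_class(fit, "tm_glm")
  expect_equal(AIC(fit), fit$aic)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_length(residuals(fit), fit$n_obs)
  expect_equal(predict(fit, type = "response"), unname(fitted(fit)))
  # cross-check the whole fit against glm on the identical design
  d <- assemble_design(w$series, side = "heat")
  ref <- glm(d$y ~ d$X - 1, family = poisson())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(AIC(fit), AIC(ref), tolerance = 1e-6)
})

test_that("percent change follows the exponential formula and is monotone", {
  expect_identical(percent_change(0), 0)
  expect_equal(percent_change(log(2)), 100)
  expect_equal(percent_change(0.0953102), 10, tolerance = 1e-3)
  b <- sort(runif(50, -1, 1))
  expect_true(all(diff(percent_change(b)) > 0))
  expect_error(percent_change(Inf), class = "tempmort_domain_error")
})

test_that("AIC indicator selection returns the minimum with mean-first ties", {
  w <- one_region_with_deaths(107L)
  sel <- select_indicator_by_aic(w$series, "heat")
  expect_equal(unname(sel$fit$aic), unname(min(sel$aic)))
  # identical indicator columns force a three-way tie, broken toward mean
  s2 <- w$series
  s2$tmax <- s2$tmean
  s2$tmin <- s2$tmean
  sel2 <- select_indicator_by_aic(s2, "heat")
  expect_equal(sel2$indicator, "mean")
  expect_equal(length(unique(round(sel2$aic, 6))), 1L)
})

test_that("the generating indicator wins the AIC comparison in most replicates", {
  # high-information design: plenty of deaths and genuinely distinct
  # tmax/tmin series, so the indicator comparison is about the exposure
  # metric rather than count noise
  wins <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    w <- one_region_with_deaths(200L + i, baseline_rate = 50,
                                half_range_noise_sd = 3)
    wins <- wins + (select_indicator_by_aic(w$series, "heat")$indicator == "mean")
  }
  expect_gte(wins / reps, 0.9)
})

test_that("negative effects are floored at zero and flagged", {
  # slope forced negative: generate with a protective heat effect
  w <- one_region_series(109L)
  cfg <- world_config(n_regions = 1L, n_stations = 1L, seed = 109L,
                      beta_heat_true = -0.05, baseline_rate = 20)
  s <- generate_mortality(w$series, cfg, label = "R01")
  e <- estimate_effects(s, "heat")
  expect_true(e$floored)
  expect_identical(e$percent_change, 0)
  expect_lt(e$percent_change_raw, 0)
  e2 <- estimate_effects(s, "heat", floor_negative = FALSE)
  expect_equal(e2$percent_change, e$percent_change_raw)
})

test_that("effects table covers every region and side and round-trips as CSV", {
  cfg <- world_config(n_regions = 3L, n_stations = 4L, seed = 113L)
  world <- generate_world(cfg)
  eff <- estimate_effects_all(world$series)
  expect_equal(nrow(eff), 6L)
  expect_setequal(eff$side, c("cold", "heat"))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_effects_csv(eff, tf)
  back <- read_effects_csv(tf)
  expect_equal(back$percent_change, eff$percent_change, tolerance = 1e-9)
})
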