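#' Ground-truth network over the region factor table
#'
#' A small discrete Bayesian network over the ten socioeconomic and
#' demographic factors (hospital beds per 10,000; per-capita years of
#' education; %uneducated; %women; %urban residents; %65+; %agriculture;
#' %industry; %service; climatic zone) plus two binary risk labels
#' (`cold_risk`, `heat_risk`). The cold label depends on education and the
#' elderly share; the heat label on hospital beds and the industrial
#' share — the dependence pattern the second analysis stage is meant to
#' recover. `intervals` maps each discrete state of a numeric factor to the
#' continuous range it is emitted from, so the supervised discretizer can
#' recover the state boundaries.
#'
#' @return List with elements `dag`, `cpts` (see [bn_model()]) and
#'   `intervals`.
#' @export
default_factor_truth <- function() {
  lh <- c("low", "high")
  nodes <- list(
    pct_urban = lh,
    education_years = lh,
    pct_uneducated = lh,
    hospital_beds = lh,
    pct_women = lh,
    pct_65plus = lh,
    pct_agriculture = lh,
    pct_industry = c("low", "middle", "high"),
    pct_service = lh,
    climatic_zone = c("tropical", "subtropical", "plateau"),
    cold_risk = c("low_risk", "high_risk"),
    heat_risk = c("low_risk", "high_risk"))
  edges <- rbind(
    c("pct_urban", "education_years"),
    c("education_years", "pct_uneducated"),
    c("pct_urban", "hospital_beds"),
    c("pct_urban", "pct_agriculture"),
    c("pct_urban", "pct_industry"),
    c("pct_urban", "pct_service"),
    c("education_years", "cold_risk"),
    c("pct_65plus", "cold_risk"),
    c("hospital_beds", "heat_risk"),
    c("pct_industry", "heat_risk"))
  # rows: parent configurations, first parent varying fastest; cols: states
  cpts <- list(
    pct_urban = c(0.6, 0.4),
    education_years = rbind(c(0.7, 0.3),    # urban low
                            c(0.2, 0.8)),   # urban high
    pct_uneducated = rbind(c(0.3, 0.7),     # edu low
                           c(0.85, 0.15)),  # edu high
    hospital_beds = rbind(c(0.75, 0.25),
                          c(0.25, 0.75)),
    pct_women = c(0.5, 0.5),
    pct_65plus = c(0.5, 0.5),
    pct_agriculture = rbind(c(0.2, 0.8),
                            c(0.8, 0.2)),
    pct_industry = rbind(c(0.5, 0.3, 0.2),
                         c(0.2, 0.4, 0.4)),
    pct_service = rbind(c(0.7, 0.3),
                        c(0.2, 0.8)),
    climatic_zone = c(0.15, 0.55, 0.30),
    # parents: education_years (fastest), pct_65plus
    cold_risk = rbind(c(0.15, 0.85),   # edu low,  65 low
                      c(0.40, 0.60),   # edu high, 65 low
                      c(0.50, 0.50),   # edu low,  65 high
                      c(0.80, 0.20)),  # edu high, 65 high
    # parents: hospital_beds (fastest), pct_industry
    heat_risk = rbind(c(0.10, 0.90),   # beds low,  industry low
                      c(0.50, 0.50),   # beds high, industry low
                      c(0.55, 0.45),   # beds low,  industry middle
                      c(0.90, 0.10),   # beds high, industry middle
                      c(0.40, 0.60),   # beds low,  industry high
                      c(0.75, 0.25)))  # beds high, industry high
  intervals <- list(
    hospital_beds = list(low = c(4.95, 30.71), high = c(30.71, 109.38)),
    education_years = list(low = c(4.50, 5.25), high = c(5.25, 12.31)),
    pct_uneducated = list(low = c(2, 10), high = c(10, 35)),
    pct_women = list(low = c(46.66, 50.08), high = c(50.08, 50.94)),
    pct_urban = list(low = c(10, 40), high = c(40, 90)),
    pct_65plus = list(low = c(3.49, 5.65), high = c(5.65, 12.68)),
    pct_agriculture = list(low = c(5, 40), high = c(40, 85)),
    pct_industry = list(low = c(1.02, 6.36), middle = c(6.36, 23.14),
                        high = c(23.14, 51.24)),
    pct_service = list(low = c(8, 25), high = c(25, 60)))
  list(dag = list(nodes = nodes, edges = edges), cpts = cpts,
       intervals = intervals)
}

#' Configuration of the synthetic study world
#'
#' Defaults describe the study conditions emulated throughout: 26 regions
#' observed for four years (1461 days from 2008-01-01), about 5
#' cardiovascular deaths per region-day at baseline, a true heat slope of
#' 0.0953 per degree C beyond the 90th-percentile threshold (a 10 percent
#' change) and a true cold slope of 0.02 per degree C below the
#' 10th-percentile threshold, weather from 40 stations with a seasonal
#' sinusoid. Temperature and humidity effects act through the short
#' (1--3 day) lag window, matching the analysis model.
#'
#' @param n_regions,n_stations,n_days,seed World dimensions and master seed.
#' @param start First day (ISO date).
#' @param lon_range,lat_range Spatial extent (degrees).
#' @param mean_temp,seasonal_amp_temp Annual mean and seasonal amplitude of
#'   station temperature (degrees C).
#' @param temp_noise_sd,station_offset_sd Daily noise and fixed per-station
#'   offset standard deviations (degrees C).
#' @param half_range,half_range_noise_sd tmax/tmin half-range about tmean.
#' @param rh_mean,rh_amp,rh_noise_sd Relative-humidity sinusoid (%).
#' @param baseline_rate Expected deaths per region-day (> 0).
#' @param beta_cold_true,beta_heat_true Log-rate slope per degree C beyond
#'   the cold/heat threshold for high-risk regions.
#' @param beta_cold_low,beta_heat_low Slopes for low-risk regions (used by
#'   [generate_world()] so that labels derived from the fitted percent
#'   changes recover the sampled truth).
#' @param dow_effects Seven multiplicative day-of-week factors, Monday
#'   first, all > 0.
#' @param humidity_effect List `(type, center, coef)`; `type` one of
#'   `"quadratic"` (log-rate term `coef * (rh - center)^2`) or `"none"`.
#' @param confounder_amp Amplitude of an optional seasonal log-rate
#'   sinusoid, off (0) by default so smooth terms face a known truth; turn
#'   on to exercise confounder control.
#' @param p_low,p_high Reference percentiles for the thresholds.
#' @param grid_cell_size Cell size of the synthetic world grid (degrees).
#' @param truth Factor-table ground truth, as [default_factor_truth()].
#' @return A validated `world_config`.
#' @export
world_config <- function(n_regions = 26L, n_stations = 40L, n_days = 1461L,
                         seed = 1L, start = "2008-01-01",
                         lon_range = c(100, 120), lat_range = c(20, 34),
                         mean_temp = 18, seasonal_amp_temp = 8,
                         temp_noise_sd = 2, station_offset_sd = 1.5,
                         half_range = 4, half_range_noise_sd = 1,
                         rh_mean = 70, rh_amp = 12, rh_noise_sd = 5,
                         baseline_rate = 5,
                         beta_cold_true = 0.02, beta_heat_true = 0.0953,
                         beta_cold_low = 0, beta_heat_low = 0.03,
                         dow_effects = c(mon = 1.02, tue = 1.00, wed = 0.99,
                                         thu = 0.99, fri = 1.00, sat = 1.01,
                                         sun = 1.03),
                         humidity_effect = list(type = "quadratic",
                                                center = 70, coef = -2e-4),
                         confounder_amp = 0,
                         p_low = 10, p_high = 90,
                         grid_cell_size = 0.5,
                         truth = default_factor_truth()) {
  if (n_days < 365)
    stop_tm("n_days must be >= 365 (got %d)", n_days,
            class = "tempmort_invalid_config")
  if (n_stations < 1 || n_regions < 1)
    stop_tm("n_stations and n_regions must be positive",
            class = "tempmort_invalid_config")
  if (baseline_rate <= 0)
    stop_tm("baseline_rate must be > 0", class = "tempmort_invalid_config")
  if (length(dow_effects) != 7L || any(dow_effects <= 0))
    stop_tm("dow_effects must be 7 positive factors",
            class = "tempmort_invalid_config")
  if (!is_acyclic(names(truth$dag$nodes), normalize_edges(truth$dag$edges)))
    stop_tm("true_dag must be acyclic", class = "tempmort_invalid_config")
  structure(as.list(environment()), class = "world_config")
}

hum_term <- function(spec, rh) {
  if (is.null(spec) || identical(spec$type, "none")) return(rep(0, length(rh)))
  if (identical(spec$type, "quadratic")) return(spec$coef * (rh - spec$center)^2)
  stop_tm("unknown humidity_effect type '%s'", spec$type,
          class = "tempmort_invalid_config")
}

#' Generate a synthetic weather-station network
#'
#' Station coordinates are uniform over the configured extent; each
#' station's daily mean temperature is
#' `mean_temp + seasonal_amp_temp * sin(2 pi day / 365.25) + offset + noise`,
#' with tmax/tmin a positive half-range above/below tmean and relative
#' humidity an opposite-phase sinusoid clipped to `[0, 100]`. Draws come
#' from a seed forked with label `"stations"`, so the station stream never
#' perturbs other generators.
#'
#' @param cfg A [world_config()].
#' @return A `station_set`: `$stations` (id, lon, lat) and `$obs`
#'   (station, date, tmean, tmax, tmin, rh).
#' @export
generate_stations <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  set.seed(fork_seed(cfg$seed, "stations"))
  ns <- cfg$n_stations; nd <- cfg$n_days
  stations <- data.frame(
    station = sprintf("S%03d", seq_len(ns)),
    lon = stats::runif(ns, cfg$lon_range[1L], cfg$lon_range[2L]),
    lat = stats::runif(ns, cfg$lat_range[1L], cfg$lat_range[2L]),
    offset = stats::rnorm(ns, 0, cfg$station_offset_sd))
  day <- seq_len(nd)
  season <- cfg$seasonal_amp_temp * sin(2 * pi * day / 365.25)
  dates <- date_seq(cfg$start, nd)
  obs <- do.call(rbind, lapply(seq_len(ns), function(i) {
    tmean <- cfg$mean_temp + season + stations$offset[i] +
      stats::rnorm(nd, 0, cfg$temp_noise_sd)
    up <- cfg$half_range + abs(stats::rnorm(nd, 0, cfg$half_range_noise_sd))
    dn <- cfg$half_range + abs(stats::rnorm(nd, 0, cfg$half_range_noise_sd))
    rh <- cfg$rh_mean + cfg$rh_amp * sin(2 * pi * day / 365.25 + pi) +
      stats::rnorm(nd, 0, cfg$rh_noise_sd)
    data.frame(station = stations$station[i], date = dates,
               tmean = tmean, tmax = tmean + up, tmin = tmean - dn,
               rh = pmin(100, pmax(0, rh)))
  }))
  structure(list(stations = stations[, c("station", "lon", "lat")],
                 obs = obs), class = "station_set")
}

#' @export
print.station_set <- function(x, ...) {
  cat(sprintf("Station set: %d stations x %d days\n",
              nrow(x$stations), length(unique(x$obs$date))))
  invisible(x)
}

# flat obs table with lon/lat merged in (the station CSV schema)
station_obs_table <- function(ss) {
  df <- merge(ss$obs, ss$stations, by = "station", sort = FALSE)
  df[order(df$station, df$date),
     c("station", "lon", "lat", "date", "tmean", "tmax", "tmin", "rh")]
}

# short-lag exposure: mean of the 1-3 day lags of x (partial at the start)
lag13_mean <- function(x) {
  n <- length(x)
  out <- numeric(n)
  out[1L] <- x[1L]
  for (t in 2:n) out[t] <- mean(x[max(1L, t - 3L):(t - 1L)])
  out
}

#' Generate daily mortality counts for one region
#'
#' Draws `deaths ~ Poisson(mu_t)` with
#' `log mu_t = log(baseline) + beta_cold * max(tau_low - T, 0) +
#' beta_heat * max(T - tau_high, 0) + log(dow factor) + humidity term`,
#' where `T` is the mean temperature over the 1--3 day lag window (the
#' short-lag exposure the analysis model uses) and the thresholds are the
#' configured percentiles of the region's daily mean temperature.
#'
#' @param exposure Data frame with `date, tmean, rh` (a region series
#'   without deaths), no missing days.
#' @param cfg A [world_config()].
#' @param beta_cold,beta_heat Log-rate slopes; default the config's
#'   high-risk truths.
#' @param label Stream label used to fork the seed; use the region id so
#'   each region has its own reproducible stream.
#' @return The exposure frame with integer `deaths` prepended, plus
#'   attributes `tau_low`, `tau_high`.
#' @export
generate_mortality <- function(exposure, cfg,
                               beta_cold = cfg$beta_cold_true,
                               beta_heat = cfg$beta_heat_true,
                               label = "region") {
  stopifnot(inherits(cfg, "world_config"))
  exposure <- exposure[order(as.Date(exposure$date)), ]
  gaps <- date_gaps(exposure$date)
  if (length(gaps))
    stop_tm("exposure has missing days: %s", paste(gaps, collapse = ", "),
            class = "tempmort_date_gap")
  tau_low <- percentile(exposure$tmean, cfg$p_low)
  tau_high <- percentile(exposure$tmean, cfg$p_high)
  tlag <- lag13_mean(exposure$tmean)
  dow <- as.integer(format(as.Date(exposure$date), "%u"))
  day <- seq_len(nrow(exposure))
  terms <- cbind(
    baseline_rate = log(cfg$baseline_rate),
    beta_cold = beta_cold * pmax(tau_low - tlag, 0),
    beta_heat = beta_heat * pmax(tlag - tau_high, 0),
    dow_effects = log(cfg$dow_effects)[dow],
    humidity_effect = hum_term(cfg$humidity_effect, exposure$rh),
    confounder_amp = cfg$confounder_amp * sin(2 * pi * day / 365.25))
  log_mu <- rowSums(terms)
  if (any(abs(log_mu) > 50)) {
    t_bad <- which.max(abs(log_mu))
    stop_tm("log mean rate out of range on day %d; largest term: %s",
            t_bad, colnames(terms)[which.max(abs(terms[t_bad, ]))],
            class = "tempmort_generation_error")
  }
  set.seed(fork_seed(cfg$seed, paste0("mortality-", label)))
  out <- cbind(data.frame(deaths = stats::rpois(nrow(exposure), exp(log_mu))),
               exposure)
  attr(out, "tau_low") <- tau_low
  attr(out, "tau_high") <- tau_high
  out
}

#' Sample the region factor table from the ground-truth network
#'
#' Each region is one ancestral-order sample from the truth network
#' (factors plus the two risk labels); numeric factors are then emitted as
#' continuous values drawn uniformly within the sampled state's interval,
#' so the supervised discretizer can recover the state boundaries.
#'
#' @param cfg A [world_config()].
#' @return List: `discrete` (region_id + factor states), `continuous`
#'   (region_id + numeric factors + climatic_zone), `labels` (region_id,
#'   cold_risk, heat_risk), `model` (the truth `bn_model`).
#' @export
generate_factor_table <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  truth <- cfg$truth
  model <- bn_model(truth$dag$nodes, truth$dag$edges, truth$cpts)
  disc <- simulate(model, nsim = cfg$n_regions,
                   seed = fork_seed(cfg$seed, "factors"))
  region_id <- sprintf("R%02d", seq_len(cfg$n_regions))
  set.seed(fork_seed(cfg$seed, "factor-jitter"))
  cont <- data.frame(region_id = region_id)
  for (f in names(truth$intervals)) {
    iv <- truth$intervals[[f]]
    lo <- vapply(disc[[f]], function(s) iv[[s]][1L], 0)
    hi <- vapply(disc[[f]], function(s) iv[[s]][2L], 0)
    cont[[f]] <- stats::runif(cfg$n_regions, lo, hi)
  }
  cont$climatic_zone <- disc$climatic_zone
  list(discrete = cbind(data.frame(region_id = region_id), disc),
       continuous = cont,
       labels = data.frame(region_id = region_id,
                           cold_risk = disc$cold_risk,
                           heat_risk = disc$heat_risk),
       model = model)
}

# partition the world extent into a grid and rectangular region masks
world_grid_masks <- function(cfg) {
  n_cols_r <- ceiling(sqrt(cfg$n_regions))
  n_rows_r <- ceiling(cfg$n_regions / n_cols_r)
  cells_per <- 2L  # 2x2 cells per region block
  grid <- make_grid(cfg$lon_range[1L], cfg$lat_range[1L],
                    cell_size = cfg$grid_cell_size,
                    n_cols = n_cols_r * cells_per,
                    n_rows = n_rows_r * cells_per)
  masks <- vector("list", cfg$n_regions)
  for (r in seq_len(cfg$n_regions)) {
    bc <- (r - 1L) %% n_cols_r
    br <- (r - 1L) %/% n_cols_r
    cols <- bc * cells_per + seq_len(cells_per)
    rows <- br * cells_per + seq_len(cells_per)
    cells <- as.vector(outer(cols, (rows - 1L) * grid$n_cols, `+`))
    masks[[r]] <- region_mask(sprintf("R%02d", r), cells, grid)
  }
  list(grid = grid, masks = masks)
}

#' Generate and write a complete synthetic study world
#'
#' Orchestrates the generators end to end: stations, a grid with one
#' rectangular mask per region, IDW/zonal region weather series, per-region
#' mortality (high-risk regions, as sampled in the factor table, get the
#' configured high-risk slopes; low-risk regions the low-risk slopes), and
#' the factor table. Writes the pipeline's input CSV schemas plus a
#' ground-truth JSON (true betas per region, DAG, CPTs, labels).
#'
#' @param cfg A [world_config()].
#' @param dir Output directory (created if needed); `NULL` returns the
#'   objects without writing.
#' @return List with `stations`, `grid`, `masks`, `series` (region series
#'   with deaths), `factors`, `truth`, and `paths` when written.
#' @export
generate_world <- function(cfg = world_config(), dir = NULL) {
  stations <- generate_stations(cfg)
  gm <- world_grid_masks(cfg)
  series <- build_region_series(stations, gm$grid, gm$masks,
                                dates = date_seq(cfg$start, cfg$n_days))
  fac <- generate_factor_table(cfg)
  betas <- data.frame(
    region_id = fac$labels$region_id,
    beta_cold = ifelse(fac$labels$cold_risk == "high_risk",
                       cfg$beta_cold_true, cfg$beta_cold_low),
    beta_heat = ifelse(fac$labels$heat_risk == "high_risk",
                       cfg$beta_heat_true, cfg$beta_heat_low))
  parts <- lapply(seq_len(nrow(betas)), function(i) {
    rid <- betas$region_id[i]
    generate_mortality(series[series$region_id == rid, ], cfg,
                       beta_cold = betas$beta_cold[i],
                       beta_heat = betas$beta_heat[i], label = rid)
  })
  series_out <- do.call(rbind, parts)
  rownames(series_out) <- NULL
  truth <- list(betas = betas, labels = fac$labels,
                dag = cfg$truth$dag, cpts = cfg$truth$cpts,
                beta_cold_true = cfg$beta_cold_true,
                beta_heat_true = cfg$beta_heat_true)
  out <- list(stations = stations, grid = gm$grid, masks = gm$masks,
              series = series_out, factors = fac, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- list(
      stations = file.path(dir, "stations.csv"),
      mortality = file.path(dir, "mortality.csv"),
      region_series = file.path(dir, "region_series.csv"),
      factors = file.path(dir, "factors.csv"),
      truth = file.path(dir, "truth.json"))
    write_station_csv(stations, p$stations)
    utils::write.csv(series_out[, c("region_id", "date", "deaths")],
                     p$mortality, row.names = FALSE, quote = FALSE)
    write_region_series_csv(series_out, p$region_series)
    utils::write.csv(fac$continuous, p$factors, row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(
      list(betas = betas, labels = fac$labels,
           dag_edges = apply(normalize_edges(cfg$truth$dag$edges), 1L,
                             paste, collapse = "->"),
           beta_cold_true = cfg$beta_cold_true,
           beta_heat_true = cfg$beta_heat_true),
      p$truth, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out$paths <- p
  }
  out
}
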