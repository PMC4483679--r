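#' Pipeline configuration
#'
#' Validates the end-to-end run configuration. Inputs are either a
#' [world_config()] (a synthetic world is generated under
#' `out_dir/synth`) or explicit file paths to a region-series CSV (with
#' deaths) and a factor CSV.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; every stochastic stage forks from it.
#' @param world A [world_config()], or `NULL` when reading files.
#' @param region_series_csv,factors_csv Input paths (ignored when `world`
#'   is given).
#' @param sides Sides to analyse.
#' @param indicator Temperature indicator (`"mean"`, `"max"`, `"min"` or
#'   `"aic"` for AIC selection).
#' @param schedule [sa_schedule()] for structure searches.
#' @param smoothing CPT pseudo-count.
#' @param manual_scheme Named list of manual discretization entries.
#' @param aggregate CV metric aggregation (`"pooled"` or `"per_fold"`).
#' @param blacklist Forbidden BN edges.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, world = NULL,
                            region_series_csv = NULL, factors_csv = NULL,
                            sides = c("cold", "heat"), indicator = "mean",
                            schedule = sa_schedule(), smoothing = 1,
                            manual_scheme = list(),
                            aggregate = c("pooled", "per_fold"),
                            blacklist = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(out_dir) == 1L, is.numeric(seed))
  if (is.null(world)) {
    if (is.null(region_series_csv) || is.null(factors_csv))
      stop_tm("either a world config or both input CSV paths are required",
              class = "tempmort_config_error")
    for (nm in c("region_series_csv", "factors_csv")) {
      p <- get(nm)
      if (!file.exists(p))
        stop_tm("input file missing: %s (%s)", p, nm,
                class = "tempmort_config_error")
    }
  } else stopifnot(inherits(world, "world_config"))
  stopifnot(all(sides %in% c("cold", "heat")), inherits(schedule, "sa_schedule"))
  structure(list(out_dir = out_dir, seed = as.integer(seed), world = world,
                 region_series_csv = region_series_csv,
                 factors_csv = factors_csv, sides = sides,
                 indicator = indicator, schedule = schedule,
                 smoothing = smoothing, manual_scheme = manual_scheme,
                 aggregate = aggregate, blacklist = blacklist),
            class = "pipeline_config")
}

pipe_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the two-stage analysis end to end
#'
#' Stages: (1) inputs (synthetic world or CSVs); (2) per-region Poisson
#' regression and percent changes; (3) risk labelling and supervised
#' discretization; (4) Bayesian-network structure and parameter learning
#' with marginal CPTs for the target's direct parents; (5) two-fold
#' cross-validation. Each stage writes its artifact under `out_dir`
#' (`effects.csv`, `discrete_<side>.csv`, `scheme_<side>.json`,
#' `bn_<side>.json`, `bn_<side>.dot`, `cv_<side>.csv`, `report.json`,
#' `report.txt`). A stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress via [message()].
#' @return List with `effects`, and per side: `training`, `scheme`,
#'   `model`, `marginals`, `cv`; plus `paths`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "inputs"
  result <- tryCatch({
    if (!is.null(config$world)) {
      pipe_log(verbose, stage, "generating synthetic world (seed %d)",
               config$world$seed)
      world <- generate_world(config$world,
                              dir = file.path(config$out_dir, "synth"))
      series <- world$series
      factors <- world$factors$continuous
    } else {
      pipe_log(verbose, stage, "reading %s", config$region_series_csv)
      series <- read_region_series_csv(config$region_series_csv)
      factors <- utils::read.csv(config$factors_csv, stringsAsFactors = FALSE)
      world <- NULL
    }

    stage <- "gam"
    pipe_log(verbose, stage, "fitting %d region(s) x {%s}",
             length(unique(series$region_id)),
             paste(config$sides, collapse = ", "))
    effects <- estimate_effects_all(series, sides = config$sides,
                                    indicator = config$indicator)
    paths <- list(effects = file.path(config$out_dir, "effects.csv"))
    write_effects_csv(effects, paths$effects)

    out <- list(effects = effects, world = world, paths = paths)
    for (side in config$sides) {
      stage <- paste0("discretize-", side)
      eff <- effects[effects$side == side, ]
      labels <- label_risk(eff$percent_change, side)
      if (nlevels(droplevels(labels)) < 2L)
        stop_tm("all regions share one %s risk class; cannot train", side,
                class = "tempmort_data_error")
      pipe_log(verbose, stage, "%d/%d regions high risk",
               sum(labels == "high_risk"), length(labels))
      scheme <- build_scheme(factors[match(eff$region_id, factors$region_id), ],
                             labels, manual = config$manual_scheme)
      disc <- apply_scheme(factors, scheme)
      training <- make_training_table(disc, effects, side)
      p_disc <- file.path(config$out_dir, paste0("discrete_", side, ".csv"))
      utils::write.csv(cbind(region_id = rownames(training),
                             as.data.frame(lapply(training, as.character))),
                       p_disc, row.names = FALSE, quote = FALSE)
      p_scheme <- file.path(config$out_dir, paste0("scheme_", side, ".json"))
      write_scheme_json(scheme, p_scheme)

      stage <- paste0("bn-", side)
      g <- sa_search(training, config$schedule,
                     seed = fork_seed(config$seed, paste0("bn-", side)),
                     blacklist = config$blacklist)
      model <- fit_cpts(g, training, smoothing = config$smoothing)
      pipe_log(verbose, stage, "learned DAG with %d edge(s), BIC %.2f",
               nrow(g$edges), attr(g, "score"))
      p_bn <- file.path(config$out_dir, paste0("bn_", side, ".json"))
      bn_to_json(model, p_bn)
      p_dot <- file.path(config$out_dir, paste0("bn_", side, ".dot"))
      dag_to_dot(model, p_dot)
      parents <- dag_parents(g, "risk")
      marginals <- lapply(parents, function(f) marginal_cpt(model, "risk", f))
      names(marginals) <- parents

      stage <- paste0("cv-", side)
      cv <- two_fold_cv(training, target = "risk", schedule = config$schedule,
                        seed = fork_seed(config$seed, paste0("cv-", side)),
                        smoothing = config$smoothing,
                        blacklist = config$blacklist,
                        aggregate = config$aggregate)
      pipe_log(verbose, stage, "accuracy %.3f", cv$metrics$accuracy[1L])
      p_cv <- file.path(config$out_dir, paste0("cv_", side, ".csv"))
      utils::write.csv(cv$metrics, p_cv, row.names = FALSE, quote = FALSE)

      out[[side]] <- list(training = training, scheme = scheme, dag = g,
                          model = model, marginals = marginals, cv = cv)
      out$paths[[paste0("discrete_", side)]] <- p_disc
      out$paths[[paste0("scheme_", side)]] <- p_scheme
      out$paths[[paste0("bn_", side)]] <- p_bn
      out$paths[[paste0("dot_", side)]] <- p_dot
      out$paths[[paste0("cv_", side)]] <- p_cv
    }

    stage <- "report"
    out$paths$report_json <- file.path(config$out_dir, "report.json")
    out$paths$report_txt <- file.path(config$out_dir, "report.txt")
    write_pipeline_report(out, config)
    out
  }, tempmort_error = function(e) {
    stop_tm("pipeline stage '%s' failed: %s", stage, conditionMessage(e),
            class = "tempmort_pipeline_error")
  })
  result
}

write_pipeline_report <- function(out, config) {
  rep <- list(seed = config$seed, sides = config$sides,
              effects = out$effects)
  txt <- c("Temperature-mortality pipeline report",
           sprintf("seed: %d", config$seed), "",
           "Per-region percent changes (per 1 degree C beyond threshold):")
  txt <- c(txt, utils::capture.output(print(out$effects, row.names = FALSE)))
  for (side in config$sides) {
    s <- out[[side]]
    rep[[side]] <- list(
      edges = if (nrow(s$dag$edges))
        apply(s$dag$edges, 1L, paste, collapse = "->") else character(0),
      bic = attr(s$dag, "score"),
      risk_parents = names(s$marginals),
      marginal_cpts = lapply(s$marginals, function(m) {
        attr(m, "undefined") <- NULL
        as.data.frame.matrix(m)
      }),
      cv = s$cv$metrics)
    txt <- c(txt, "", sprintf("== %s network ==", side),
             sprintf("edges: %s", paste(rep[[side]]$edges, collapse = ", ")),
             sprintf("direct parents of risk: %s",
                     paste(names(s$marginals), collapse = ", ")))
    for (f in names(s$marginals)) {
      txt <- c(txt, sprintf("P(risk | %s):", f),
               utils::capture.output(print(round(s$marginals[[f]], 3))))
    }
    txt <- c(txt, "2-fold cross-validation:",
             utils::capture.output(print(s$cv$metrics, row.names = FALSE)))
  }
  jsonlite::write_json(rep, out$paths$report_json, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", force = TRUE)
  writeLines(txt, out$paths$report_txt)
  invisible(out$paths$report_json)
}
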