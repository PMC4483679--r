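#' Confusion matrix of actual vs predicted states
#'
#' @param actual,predicted Vectors of class labels (coerced to a common
#'   factor).
#' @return A contingency table, rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted) {
  lev <- union(levels(factor(actual)), levels(factor(predicted)))
  table(actual = factor(actual, levels = lev),
        predicted = factor(predicted, levels = lev))
}

#' Detection/false-alarm/accuracy metrics for one target state
#'
#' For the given state: `pd = TP / (TP + FN)` (probability of detection,
#' i.e. recall for the state), `pf = FP / (FP + TN)` (probability of false
#' alarm: the rate at which actual other-state instances are predicted as
#' the state), and `accuracy = (TP + TN) / total` (identical for every
#' state of a binary target). A metric with a zero denominator is reported
#' as `NA`, never as 0.
#'
#' @param cm A [confusion_matrix()].
#' @param state The target state.
#' @return One-row data frame: `state, pd, pf, accuracy, tp, fn, fp, tn`.
#' @export
cv_metrics <- function(cm, state) {
  if (sum(cm) == 0)
    stop_tm("empty confusion matrix", class = "tempmort_domain_error")
  if (!state %in% rownames(cm))
    stop_tm("unknown state '%s'", state, class = "tempmort_domain_error")
  tp <- cm[state, state]
  fn <- sum(cm[state, ]) - tp
  fp <- sum(cm[, state]) - tp
  tn <- sum(cm) - tp - fn - fp
  data.frame(state = state,
             pd = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             pf = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
             accuracy = (tp + tn) / sum(cm),
             tp = tp, fn = fn, fp = fp, tn = tn,
             stringsAsFactors = FALSE)
}

metrics_table <- function(cm) {
  do.call(rbind, lapply(rownames(cm), function(s) cv_metrics(cm, s)))
}

#' Enumerate integer confusion matrices consistent with printed metrics
#'
#' Searches all binary confusion matrices with `n` instances and a fixed
#' actual split for those whose pd and pf (for the first state) match given
#' values when rounded to `digits` decimals. Used to check that printed
#' pd/pf/accuracy triples are arithmetically consistent.
#'
#' @param n Total instances.
#' @param n_state Actual count of the state of interest; `n - n_state`
#'   belong to the other state.
#' @param pd,pf Printed values to match.
#' @param digits Printed precision.
#' @return Data frame of matching `tp, fn, fp, tn` rows with their exact
#'   `pd, pf, accuracy`.
#' @export
consistent_confusions <- function(n, n_state, pd, pf, digits = 3L) {
  out <- list()
  n_other <- n - n_state
  for (tp in 0:n_state) for (fp in 0:n_other) {
    fn <- n_state - tp
    tn <- n_other - fp
    pdv <- if (n_state > 0) tp / n_state else NA_real_
    pfv <- if (n_other > 0) fp / n_other else NA_real_
    if (!is.na(pdv) && !is.na(pfv) &&
        round(pdv, digits) == round(pd, digits) &&
        round(pfv, digits) == round(pf, digits))
      out[[length(out) + 1L]] <- data.frame(
        tp = tp, fn = fn, fp = fp, tn = tn,
        pd = pdv, pf = pfv, accuracy = (tp + tn) / n)
  }
  if (!length(out)) return(data.frame(tp = integer(0), fn = integer(0),
                                      fp = integer(0), tn = integer(0),
                                      pd = numeric(0), pf = numeric(0),
                                      accuracy = numeric(0)))
  do.call(rbind, out)
}

# seeded stratified 2-fold assignment; fold sizes differ by at most 1 and
# class proportions are preserved to within one region
stratified_folds <- function(classes, seed) {
  n <- length(classes)
  set.seed(fork_seed(seed, "cv-folds"))
  fold <- integer(n)
  lev <- levels(factor(classes))
  base <- vapply(lev, function(l) sum(classes == l) %/% 2L, 1L)
  rem <- vapply(lev, function(l) sum(classes == l) %% 2L, 1L)
  # distribute the odd classes' leftover members so fold 1 gets floor(n/2)
  extra_needed <- n %/% 2L - sum(base)
  gets_extra <- rep(FALSE, length(lev))
  if (extra_needed > 0) {
    odd <- which(rem == 1L)
    pick <- if (length(odd) == 1L) odd else sample(odd, extra_needed)
    gets_extra[pick] <- TRUE
  }
  for (k in seq_along(lev)) {
    idx <- sample(which(classes == lev[k]))
    n1 <- base[k] + as.integer(gets_extra[k])
    fold[idx] <- c(rep(1L, n1), rep(2L, length(idx) - n1))
  }
  fold
}

#' Two-fold cross-validation of the Bayesian-network risk classifier
#'
#' Rows are split into two folds by seeded stratified random assignment
#' (class proportions preserved to within one region). For each fold the
#' network structure and CPTs are learned on the other fold and the
#' held-out regions' target states predicted from their factor states, so
#' every region is predicted exactly once. Metrics are pooled over the two
#' folds' confusion matrices by default; `aggregate = "per_fold"` averages
#' the per-fold metrics instead.
#'
#' @param data Discrete training table (factor columns + target), region
#'   ids in the row names.
#' @param target Target column name.
#' @param schedule [sa_schedule()] for the structure searches.
#' @param seed Integer seed (folds and searches fork from it).
#' @param smoothing CPT pseudo-count.
#' @param blacklist Forbidden edges, as in [sa_search()].
#' @param aggregate `"pooled"` or `"per_fold"`.
#' @return List: `predictions` (region, fold, actual, predicted),
#'   `confusion` (pooled), `metrics` (per state), `models` (per fold).
#' @export
two_fold_cv <- function(data, target = "risk", schedule = sa_schedule(),
                        seed, smoothing = 1, blacklist = NULL,
                        aggregate = c("pooled", "per_fold")) {
  aggregate <- match.arg(aggregate)
  if (missing(seed)) stop_tm("seed is required", class = "tempmort_config_error")
  if (nrow(data) < 4L)
    stop_tm("need >= 4 rows for 2-fold CV", class = "tempmort_data_error")
  classes <- factor(data[[target]])
  if (nlevels(droplevels(classes)) < 2L)
    stop_tm("both target classes must be present",
            class = "tempmort_data_error")
  fold <- stratified_folds(classes, seed)
  models <- list()
  preds <- list()
  cms <- list()
  for (k in 1:2) {
    train <- data[fold != k, , drop = FALSE]
    test <- data[fold == k, , drop = FALSE]
    if (nlevels(droplevels(factor(train[[target]]))) < 2L)
      stop_tm("training fold %d misses a target class", k,
              class = "tempmort_stratification_error")
    g <- sa_search(train, schedule,
                   seed = fork_seed(seed, paste0("cv-structure-", k)),
                   blacklist = blacklist)
    model <- fit_cpts(g, train, smoothing = smoothing)
    models[[k]] <- model
    predicted <- vapply(seq_len(nrow(test)), function(i) {
      ev <- vapply(setdiff(names(test), target), function(v)
        as.character(test[[v]][i]), "")
      names(ev) <- setdiff(names(test), target)
      predict(model, target = target, evidence = ev)$state
    }, "")
    preds[[k]] <- data.frame(region = rownames(test), fold = k,
                             actual = as.character(test[[target]]),
                             predicted = predicted,
                             stringsAsFactors = FALSE)
    cms[[k]] <- confusion_matrix(preds[[k]]$actual, preds[[k]]$predicted)
  }
  predictions <- do.call(rbind, preds)
  pooled <- confusion_matrix(predictions$actual, predictions$predicted)
  metrics <- if (aggregate == "pooled") {
    metrics_table(pooled)
  } else {
    m1 <- metrics_table(cms[[1L]]); m2 <- metrics_table(cms[[2L]])
    out <- m1
    for (col in c("pd", "pf", "accuracy"))
      out[[col]] <- (m1[[col]] + m2[[col]]) / 2
    out[c("tp", "fn", "fp", "tn")] <- m1[c("tp", "fn", "fp", "tn")] +
      m2[c("tp", "fn", "fp", "tn")]
    out
  }
  list(predictions = predictions, confusion = pooled, metrics = metrics,
       models = models, fold = fold)
}
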