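entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

class_counts <- function(labels) as.numeric(table(labels))

#' Supervised entropy-minimization splits (Fayyad-Irani MDLP)
#'
#' Recursive binary splitting of a continuous factor against a binary risk
#' label. Candidate cuts are midpoints between adjacent distinct values
#' whose label composition differs (boundary points); the cut with maximal
#' information gain is accepted when the gain passes the minimum
#' description length criterion
#' `gain > (log2(N-1) + log2(3^k - 2) - (k E(S) - k1 E(S1) - k2 E(S2))) / N`,
#' and each side is then split recursively. When the MDL criterion rejects
#' every cut, a single median cut is returned as fallback (flagged in the
#' `fallback` attribute) so downstream discretization always has at least
#' two states.
#'
#' @param x Continuous values (>= 2 distinct).
#' @param labels Binary labels, both classes present.
#' @param fallback Use the median-cut fallback when no cut is accepted.
#' @return Sorted numeric cut points, possibly with attribute
#'   `fallback = TRUE`.
#' @export
supervised_splits <- function(x, labels, fallback = TRUE) {
  stopifnot(length(x) == length(labels))
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop_tm("both label classes must be present",
            class = "tempmort_degenerate_labels")
  if (length(unique(x)) < 2L)
    stop_tm("need >= 2 distinct values", class = "tempmort_data_error")
  ord <- order(x)
  cuts <- mdlp_recurse(x[ord], labels[ord])
  if (!length(cuts) && fallback) {
    cuts <- stats::median(x)
    attr(cuts, "fallback") <- TRUE
    return(cuts)
  }
  sort(cuts)
}

# candidate midpoints between adjacent distinct values whose label
# composition differs (or either value carries mixed labels)
boundary_candidates <- function(x, labels) {
  u <- unique(x)  # x sorted
  if (length(u) < 2L) return(numeric(0))
  comp <- lapply(u, function(v) sort(as.integer(unique(labels[x == v]))))
  keep <- vapply(seq_len(length(u) - 1L), function(i) {
    !identical(comp[[i]], comp[[i + 1L]]) ||
      length(comp[[i]]) > 1L || length(comp[[i + 1L]]) > 1L
  }, TRUE)
  ((u[-length(u)] + u[-1L]) / 2)[keep]
}

mdlp_recurse <- function(x, labels) {
  n <- length(x)
  cand <- boundary_candidates(x, labels)
  if (!length(cand)) return(numeric(0))
  ent_s <- entropy_bits(class_counts(labels))
  best <- NULL
  best_e <- Inf
  for (c in cand) {
    l <- x < c
    e <- (sum(l) * entropy_bits(class_counts(labels[l])) +
          sum(!l) * entropy_bits(class_counts(labels[!l]))) / n
    if (e < best_e) {
      best_e <- e
      best <- c
    }
  }
  gain <- ent_s - best_e
  l <- x < best
  k <- nlevels(droplevels(labels))
  k1 <- nlevels(droplevels(labels[l]))
  k2 <- nlevels(droplevels(labels[!l]))
  delta <- log2(3^k - 2) -
    (k * ent_s - k1 * entropy_bits(class_counts(labels[l])) -
       k2 * entropy_bits(class_counts(labels[!l])))
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  c(mdlp_recurse(x[l], droplevels(labels[l])),
    best,
    mdlp_recurse(x[!l], droplevels(labels[!l])))
}

state_labels <- function(k) {
  switch(as.character(k),
         "1" = "all",
         "2" = c("low", "high"),
         "3" = c("low", "middle", "high"),
         paste0("state", seq_len(k)))
}

#' Build a discretization scheme for a factor table
#'
#' Numeric factors get supervised MDLP cuts against the risk labels (with
#' median fallback); categorical factors pass through. Manual entries
#' override the automatic cuts, e.g. to reproduce published intervals.
#'
#' @param factors Factor table (`region_id` + factor columns).
#' @param labels Binary risk labels aligned with the rows.
#' @param manual Named list of manual entries, each either a numeric vector
#'   of cuts or a [manual_intervals()] result.
#' @return A `tm_scheme`: per factor, `cuts`, `right_closed` (per cut:
#'   does the boundary value belong to the lower state?), `states`, and
#'   `type` (`"numeric"` or `"categorical"`).
#' @export
build_scheme <- function(factors, labels, manual = list()) {
  scheme <- list()
  for (f in setdiff(names(factors), "region_id")) {
    if (!is.null(manual[[f]])) {
      m <- manual[[f]]
      if (is.numeric(m) && is.null(attr(m, "right_closed")))
        m <- structure(list(cuts = sort(m),
                            right_closed = rep(FALSE, length(m))),
                       class = "tm_intervals")
      scheme[[f]] <- list(type = "numeric", cuts = m$cuts,
                          right_closed = m$right_closed,
                          bounds = m$bounds %||% NULL,
                          states = m$states %||%
                            state_labels(length(m$cuts) + 1L))
    } else if (is.numeric(factors[[f]])) {
      cuts <- supervised_splits(factors[[f]], labels)
      scheme[[f]] <- list(type = "numeric", cuts = as.numeric(cuts),
                          right_closed = rep(FALSE, length(cuts)),
                          fallback = isTRUE(attr(cuts, "fallback")),
                          states = state_labels(length(cuts) + 1L))
    } else {
      scheme[[f]] <- list(type = "categorical",
                          states = sort(unique(as.character(factors[[f]]))))
    }
  }
  structure(scheme, class = "tm_scheme")
}

#' Parse printed interval notation into a manual scheme entry
#'
#' Honors bracket types verbatim: in `"[1.02, 6.36], (6.36, 23.14]"` the
#' boundary 6.36 belongs to the *lower* state (its left bracket is open),
#' whereas the default automatic convention sends boundary values up.
#'
#' @param intervals Character vector of intervals in printed order, e.g.
#'   `c("[5.18, 5.25]", "(5.25, 12.31]")`.
#' @param states Optional state names (default low/middle/high style).
#' @return A `tm_intervals` entry for [build_scheme()]'s `manual` list.
#' @export
manual_intervals <- function(intervals, states = NULL) {
  m <- regmatches(intervals,
                  regexec("^\\s*([\\[(])\\s*([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+]+)\\s*([])])\\s*$",
                          intervals))
  if (any(vapply(m, length, 1L) != 5L))
    stop_tm("cannot parse interval notation", class = "tempmort_config_error")
  lo <- vapply(m, function(g) as.numeric(g[3L]), 0)
  hi <- vapply(m, function(g) as.numeric(g[4L]), 0)
  left_open <- vapply(m, function(g) g[2L] == "(", TRUE)
  k <- length(intervals)
  if (k < 1L || any(lo[-1L] != hi[-k]))
    stop_tm("intervals must abut in increasing order",
            class = "tempmort_config_error")
  structure(list(cuts = hi[-k],
                 # interior boundary belongs to the lower state iff the
                 # upper interval's left bracket is open
                 right_closed = left_open[-1L],
                 bounds = c(lo[1L], hi[k]),
                 states = states %||% state_labels(k)),
            class = "tm_intervals")
}

#' Apply a discretization scheme to a factor table
#'
#' Automatic cuts use the half-open `[a, b)` convention: a value equal to a
#' cut belongs to the upper state. Manual interval entries follow their
#' printed brackets. Values outside a manual entry's outermost interval are
#' extended to the nearest state with a warning.
#'
#' @param table Factor table (`region_id` + factor columns).
#' @param scheme A [build_scheme()] result.
#' @return Data frame of ordered-factor columns (plus `region_id`).
#' @export
apply_scheme <- function(table, scheme) {
  out <- data.frame(region_id = table$region_id %||%
                      sprintf("R%02d", seq_len(nrow(table))))
  for (f in names(scheme)) {
    sc <- scheme[[f]]
    if (is.null(table[[f]]))
      stop_tm("factor '%s' missing from table", f,
              class = "tempmort_data_error")
    if (sc$type == "categorical") {
      out[[f]] <- factor(as.character(table[[f]]), levels = sc$states)
      next
    }
    x <- table[[f]]
    if (!is.null(sc$bounds) &&
        any(x < sc$bounds[1L] | x > sc$bounds[2L], na.rm = TRUE))
      warning(sprintf("factor '%s': value(s) outside [%g, %g] extended to the nearest state",
                      f, sc$bounds[1L], sc$bounds[2L]), call. = FALSE)
    idx <- rep(1L, length(x))
    for (k in seq_along(sc$cuts)) {
      up <- if (isTRUE(sc$right_closed[k])) x > sc$cuts[k] else x >= sc$cuts[k]
      idx <- idx + up
    }
    out[[f]] <- factor(sc$states[idx], levels = sc$states, ordered = TRUE)
  }
  out
}

#' Binary risk label from an estimated percent change
#'
#' Cold side: high risk iff the percent change per 1 degree C below the
#' cold threshold is at least 1; heat side: at least 10 (the "10% or more"
#' rule). Percent changes are assumed already floored at 0 where negative.
#'
#' @param percent_change Numeric vector of percent changes.
#' @param side `"cold"` or `"heat"` (scalar or vector).
#' @return Factor with levels `low_risk`, `high_risk` (low first).
#' @export
label_risk <- function(percent_change, side) {
  if (!all(side %in% c("cold", "heat")))
    stop_tm("side must be 'cold' or 'heat'", class = "tempmort_domain_error")
  thr <- ifelse(side == "cold", 1, 10)
  factor(ifelse(percent_change >= thr, "high_risk", "low_risk"),
         levels = c("low_risk", "high_risk"))
}

#' Assemble the BN training table for one side
#'
#' Joins the discretized factors with the risk labels derived from the
#' effects table.
#'
#' @param discrete Discretized factor table from [apply_scheme()].
#' @param effects Effects table from [estimate_effects_all()].
#' @param side `"cold"` or `"heat"`.
#' @return Data frame: factor columns plus a `risk` column, one row per
#'   region, `region_id` in the row names.
#' @export
make_training_table <- function(discrete, effects, side) {
  eff <- effects[effects$side == side, ]
  m <- merge(discrete, eff[, c("region_id", "percent_change")],
             by = "region_id")
  m$risk <- label_risk(m$percent_change, side)
  rownames(m) <- m$region_id
  m[, setdiff(names(m), c("region_id", "percent_change"))]
}

#' Read / write a discretization scheme as JSON
#'
#' @param scheme A `tm_scheme`.
#' @param path File path.
#' @return Scheme (reader) or `path` invisibly (writer).
#' @export
write_scheme_json <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(obj, function(sc) {
    sc <- as.list(sc)
    if (!is.null(sc$cuts)) sc$cuts <- as.numeric(sc$cuts)
    sc
  }), class = "tm_scheme")
}
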