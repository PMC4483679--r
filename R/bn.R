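#' Directed acyclic graph over discrete variables
#'
#' Constructs the graph half of a discrete Bayesian network: a set of named
#' nodes, each with an ordered vector of state labels, and a set of directed
#' edges. The constructor validates acyclicity and rejects self-loops and
#' duplicate edges.
#'
#' @param nodes Named list; each element is the character vector of state
#'   labels of that variable, in a fixed order (the first state is the
#'   tie-break winner in [predict.bn_model()]).
#' @param edges Two-column character matrix (or data.frame) of directed
#'   edges, `from` in column 1, `to` in column 2. May have zero rows.
#' @return An object of class `bn_dag`.
#' @export
#' @examples
#' dag(list(a = c("0", "1"), b = c("0", "1")), rbind(c("a", "b")))
dag <- function(nodes, edges = NULL) {
  stopifnot(is.list(nodes), length(names(nodes)) == length(nodes))
  if (any(duplicated(names(nodes))))
    stop_tm("duplicate node names", class = "tempmort_invalid_dag")
  if (any(vapply(nodes, length, 1L) < 2L))
    stop_tm("every node needs >= 2 states", class = "tempmort_invalid_dag")
  edges <- normalize_edges(edges)
  bad <- !(edges[, 1L] %in% names(nodes)) | !(edges[, 2L] %in% names(nodes))
  if (any(bad))
    stop_tm("edge endpoints not in node set: %s",
            paste(edges[bad, 1L], edges[bad, 2L], sep = "->", collapse = ", "),
            class = "tempmort_invalid_dag")
  if (any(edges[, 1L] == edges[, 2L]))
    stop_tm("self-loops are not allowed", class = "tempmort_invalid_dag")
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L])))
    stop_tm("duplicate edges", class = "tempmort_invalid_dag")
  if (is.null(topo_order(names(nodes), edges)))
    stop_tm("graph is cyclic", class = "tempmort_invalid_dag")
  structure(list(nodes = nodes, edges = edges), class = "bn_dag")
}

#' @rdname dag
#' @export
empty_dag <- function(nodes) dag(nodes, NULL)

normalize_edges <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0L)
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  colnames(edges) <- c("from", "to")
  edges
}

# Kahn's algorithm; NULL if cyclic
topo_order <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(edges[, 2L])
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  queue <- nodes[indeg == 0L]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    if (nrow(edges)) {
      ch <- edges[edges[, 1L] == v, 2L]
      for (w in ch) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) queue <- c(queue, w)
      }
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

is_acyclic <- function(nodes, edges) !is.null(topo_order(nodes, edges))

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("Discrete DAG: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L]), sep = "\n")
  invisible(x)
}

dag_parents <- function(dag, node) dag$edges[dag$edges[, 2L] == node, 1L]

#' Skeleton and v-structures; Markov-equivalence comparison
#'
#' Two DAGs represent the same set of conditional-independence constraints
#' (the same Markov-equivalence class) iff they share the same skeleton
#' (undirected adjacencies) and the same v-structures (colliders
#' `a -> c <- b` with `a`, `b` non-adjacent).
#'
#' @param d1,d2 `bn_dag` objects over the same node set.
#' @return `TRUE` or `FALSE`.
#' @export
same_equivalence_class <- function(d1, d2) {
  setequal(names(d1$nodes), names(d2$nodes)) &&
    setequal(dag_skeleton(d1), dag_skeleton(d2)) &&
    setequal(dag_v_structures(d1), dag_v_structures(d2))
}

dag_skeleton <- function(dag) {
  if (!nrow(dag$edges)) return(character(0))
  unique(apply(dag$edges, 1L,
               function(e) paste(sort(e), collapse = "--")))
}

dag_v_structures <- function(dag) {
  e <- dag$edges
  if (nrow(e) < 2L) return(character(0))
  adj <- dag_skeleton(dag)
  out <- character(0)
  for (c in unique(e[, 2L])) {
    pa <- e[e[, 2L] == c, 1L]
    if (length(pa) < 2L) next
    for (i in seq_len(length(pa) - 1L)) for (j in (i + 1L):length(pa)) {
      ab <- sort(c(pa[i], pa[j]))
      if (!paste(ab, collapse = "--") %in% adj)
        out <- c(out, paste(ab[1L], "->", c, "<-", ab[2L]))
    }
  }
  out
}

## ---------------------------------------------------------------- scoring

# data columns coerced to factors with the dag's state levels
bn_data_factors <- function(dag, data) {
  for (v in names(dag$nodes)) {
    if (is.null(data[[v]]))
      stop_tm("variable '%s' missing from data", v, class = "tempmort_data_error")
    f <- factor(as.character(data[[v]]), levels = dag$nodes[[v]])
    if (anyNA(f))
      stop_tm("variable '%s' has states outside its declared set", v,
              class = "tempmort_data_error")
    data[[v]] <- f
  }
  data[names(dag$nodes)]
}

# BIC family score (natural log): loglik at MLE minus log(n)/2 * (r-1) q
family_score <- function(child, parents, data) {
  n <- nrow(data)
  r <- nlevels(data[[child]])
  if (length(parents) == 0L) {
    cnt <- table(data[[child]])
    q <- 1L
    ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0] / n))
  } else {
    cfg <- interaction(data[parents], drop = FALSE, lex.order = FALSE)
    cnt <- table(cfg, data[[child]])
    q <- nlevels(cfg)
    rs <- rowSums(cnt)
    pos <- cnt > 0
    ll <- sum(cnt[pos] * log(cnt[pos] / rs[row(cnt)[pos]]))
  }
  ll - log(n) / 2 * (r - 1) * q
}

#' BIC score of a DAG on a complete discrete table
#'
#' Decomposable Bayesian information criterion under natural logs:
#' `sum_i [ loglik_i - log(n)/2 * (r_i - 1) * q_i ]`, where `loglik_i` is
#' the multinomial log-likelihood of node `i` given its parents at the
#' maximum-likelihood estimate, `r_i` its number of states and `q_i` the
#' number of parent configurations. Higher is better.
#'
#' @param dag A [dag()].
#' @param data Data frame of discrete observations (character or factor),
#'   one column per node, no missing cells.
#' @return Scalar score.
#' @export
bic_score <- function(dag, data) {
  data <- bn_data_factors(dag, data)
  if (nrow(data) == 0L)
    stop_tm("empty data", class = "tempmort_data_error")
  sum(vapply(names(dag$nodes),
             function(v) family_score(v, dag_parents(dag, v), data), 0))
}

## ------------------------------------------------------------- SA search

#' Simulated-annealing schedule
#'
#' @param t_init Initial temperature (> `t_stop`).
#' @param cooling Geometric cooling factor per temperature step, in (0, 1).
#' @param moves_per_temp Moves attempted at each temperature.
#' @param t_stop Stop temperature (> 0).
#' @param max_iter Hard cap on total moves.
#' @return Object of class `sa_schedule`.
#' @export
sa_schedule <- function(t_init = 1.0, cooling = 0.995, moves_per_temp = 50L,
                        t_stop = 1e-3, max_iter = 20000L) {
  stopifnot(cooling > 0, cooling < 1, t_init > t_stop, t_stop > 0,
            moves_per_temp >= 1, max_iter >= 0)
  structure(list(t_init = t_init, cooling = cooling,
                 moves_per_temp = as.integer(moves_per_temp),
                 t_stop = t_stop, max_iter = as.integer(max_iter)),
            class = "sa_schedule")
}

edge_in <- function(edges, from, to)
  any(edges[, 1L] == from & edges[, 2L] == to)

edge_drop <- function(edges, from, to)
  edges[!(edges[, 1L] == from & edges[, 2L] == to), , drop = FALSE]

#' Learn a DAG by simulated annealing over single-edge moves
#'
#' Stochastic search over DAGs scored by [bic_score()]. Moves are
#' single-edge additions, deletions and reversals drawn uniformly among the
#' legal (acyclicity-preserving, blacklist-respecting) moves; a better
#' candidate is always accepted, a worse one with probability
#' `exp(delta / temperature)`. The best-scoring DAG ever visited is
#' returned, so the search can never do worse than its starting graph.
#'
#' @param data Data frame of discrete observations.
#' @param schedule An [sa_schedule()].
#' @param seed Integer seed (mandatory: the search is stochastic).
#' @param init Starting `bn_dag`; defaults to the empty graph on the
#'   columns of `data` with states taken from the observed levels.
#' @param whitelist Two-column matrix of edges that must be present and are
#'   never removed or reversed.
#' @param blacklist Two-column matrix of directed edges that may never be
#'   present.
#' @return The best `bn_dag` visited, with attributes `score` (its BIC) and
#'   `iterations`.
#' @export
sa_search <- function(data, schedule = sa_schedule(), seed,
                      init = NULL, whitelist = NULL, blacklist = NULL) {
  stopifnot(inherits(schedule, "sa_schedule"))
  if (missing(seed)) stop_tm("seed is required", class = "tempmort_config_error")
  if (ncol(data) < 2L)
    stop_tm("need >= 2 variables", class = "tempmort_data_error")
  if (is.null(init)) {
    # factor columns keep their declared state sets even when a state is
    # absent from this subset (matters for CV training folds)
    lev <- lapply(data, function(x)
      if (is.factor(x)) levels(x) else levels(factor(as.character(x))))
    init <- empty_dag(lev)
  }
  whitelist <- normalize_edges(whitelist)
  blacklist <- normalize_edges(blacklist)
  if (nrow(whitelist)) {
    ed <- init$edges
    for (k in seq_len(nrow(whitelist)))
      if (!edge_in(ed, whitelist[k, 1L], whitelist[k, 2L]))
        ed <- rbind(ed, whitelist[k, ])
    init <- dag(init$nodes, ed)
  }
  data <- bn_data_factors(init, data)
  nodes <- names(init$nodes)
  nn <- length(nodes)

  cache <- new.env(parent = emptyenv())
  fam <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- family_score(child, parents, data)
      cache[[key]] <- val
    }
    val
  }
  node_score <- function(edges, v) fam(v, edges[edges[, 2L] == v, 1L])
  total <- function(edges) sum(vapply(nodes, function(v) node_score(edges, v), 0))

  cur <- init$edges
  cur_score <- total(cur)
  best <- cur
  best_score <- cur_score

  set.seed(fork_seed(seed, "sa-search"))
  temp <- schedule$t_init
  iter <- 0L
  types <- c("add", "delete", "reverse")
  while (temp >= schedule$t_stop && iter < schedule$max_iter) {
    for (m in seq_len(schedule$moves_per_temp)) {
      iter <- iter + 1L
      if (iter > schedule$max_iter) break
      mv <- NULL
      for (try in 1:200) {
        ij <- sample.int(nn, 2L)
        from <- nodes[ij[1L]]; to <- nodes[ij[2L]]
        type <- types[sample.int(3L, 1L)]
        present <- edge_in(cur, from, to)
        if (type == "add") {
          if (present || edge_in(blacklist, from, to)) next
          cand <- rbind(cur, c(from, to))
          if (!is_acyclic(nodes, cand)) next
          mv <- list(cand = cand, touched = to)
        } else if (type == "delete") {
          if (!present || edge_in(whitelist, from, to)) next
          mv <- list(cand = edge_drop(cur, from, to), touched = to)
        } else {
          if (!present || edge_in(whitelist, from, to) ||
              edge_in(blacklist, to, from)) next
          cand <- rbind(edge_drop(cur, from, to), c(to, from))
          if (!is_acyclic(nodes, cand)) next
          mv <- list(cand = cand, touched = c(from, to))
        }
        break
      }
      if (is.null(mv)) next  # no legal move found in the attempt budget
      delta <- sum(vapply(mv$touched, function(v) node_score(mv$cand, v), 0)) -
        sum(vapply(mv$touched, function(v) node_score(cur, v), 0))
      if (delta >= 0 || stats::runif(1L) < exp(delta / temp)) {
        cur <- mv$cand
        cur_score <- cur_score + delta
        if (cur_score > best_score) {
          best <- cur
          best_score <- cur_score
        }
      }
    }
    temp <- temp * schedule$cooling
  }
  out <- dag(init$nodes, best)
  attr(out, "score") <- best_score
  attr(out, "iterations") <- iter
  out
}

## ----------------------------------------------------------- CPTs, model

# parent-state-major row index: first parent varies fastest
cfg_index <- function(state_pos, cards) {
  idx <- rep(1L, length(state_pos[[1L]]))
  mult <- 1L
  for (k in seq_along(cards)) {
    idx <- idx + (state_pos[[k]] - 1L) * mult
    mult <- mult * cards[k]
  }
  idx
}

cfg_labels <- function(parents, nodes) {
  if (!length(parents)) return("")
  g <- expand.grid(lapply(parents, function(p) nodes[[p]]),
                   stringsAsFactors = FALSE)
  apply(g, 1L, paste, collapse = "|")
}

#' Estimate conditional probability tables for a DAG
#'
#' Maximum-likelihood CPT estimation with optional additive (Laplace)
#' smoothing: `P(x_i = s | pa = c) = (N(s, c) + a) / (N(c) + a r_i)` with
#' pseudo-count `a`. With `smoothing = 0` a parent configuration never seen
#' in the data gets a uniform row.
#'
#' @param dag A [dag()].
#' @param data Discrete data frame.
#' @param smoothing Pseudo-count `a >= 0`; default 1 (Laplace).
#' @return Object of class `bn_model`: the pair (graph, CPT set). Each CPT
#'   is a matrix with one row per parent configuration (first parent
#'   varying fastest) and one column per child state.
#' @export
fit_cpts <- function(dag, data, smoothing = 1) {
  stopifnot(smoothing >= 0)
  data <- bn_data_factors(dag, data)
  cpts <- list()
  for (v in names(dag$nodes)) {
    pa <- dag_parents(dag, v)
    r <- length(dag$nodes[[v]])
    if (length(pa) == 0L) {
      cnt <- matrix(as.numeric(table(data[[v]])), nrow = 1L)
    } else {
      cfg <- interaction(data[pa], drop = FALSE, lex.order = FALSE)
      cnt <- unclass(table(cfg, data[[v]]))
      dim(cnt) <- c(nlevels(cfg), r)
    }
    rs <- rowSums(cnt)
    prob <- (cnt + smoothing) / (rs + smoothing * r)
    if (smoothing == 0 && any(rs == 0))
      prob[rs == 0, ] <- 1 / r
    dimnames(prob) <- list(cfg_labels(pa, dag$nodes), dag$nodes[[v]])
    cpts[[v]] <- list(parents = pa, prob = prob)
  }
  structure(list(dag = dag, cpts = cpts), class = "bn_model")
}

#' @export
print.bn_model <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network: %d nodes, %d edges\n",
              length(x$dag$nodes), nrow(x$dag$edges)))
  for (v in names(x$cpts)) {
    pa <- x$cpts[[v]]$parents
    cat(sprintf("  %s%s: %d states, %d parent configuration(s)\n", v,
                if (length(pa)) paste0(" | ", paste(pa, collapse = ", ")) else "",
                ncol(x$cpts[[v]]$prob), nrow(x$cpts[[v]]$prob)))
  }
  invisible(x)
}

validate_cpts <- function(model, tol = 1e-9) {
  for (v in names(model$cpts)) {
    p <- model$cpts[[v]]$prob
    if (any(p < -tol) || any(abs(rowSums(p) - 1) > tol))
      stop_tm("CPT of '%s' has a row not summing to 1", v,
              class = "tempmort_invalid_cpt")
  }
  invisible(TRUE)
}

#' Build a Bayesian network from explicit CPTs
#'
#' Assembles a `bn_model` from a node/state list, an edge list and
#' hand-specified CPT matrices (rows = parent configurations with the first
#' parent varying fastest, columns = child states). Rows must sum to 1
#' within `1e-9`.
#'
#' @param nodes,edges As in [dag()].
#' @param cpts Named list: for each node a matrix (or vector for parentless
#'   nodes) of conditional probabilities.
#' @return A `bn_model`.
#' @export
bn_model <- function(nodes, edges, cpts) {
  g <- dag(nodes, edges)
  out <- list(dag = g, cpts = list())
  for (v in names(nodes)) {
    pa <- dag_parents(g, v)
    q <- prod(vapply(pa, function(p) length(nodes[[p]]), 1L))
    p <- cpts[[v]]
    if (is.null(p)) stop_tm("no CPT for node '%s'", v,
                            class = "tempmort_invalid_cpt")
    p <- matrix(as.numeric(p), nrow = q, ncol = length(nodes[[v]]),
                dimnames = list(cfg_labels(pa, nodes), nodes[[v]]))
    out$cpts[[v]] <- list(parents = pa, prob = p)
  }
  out <- structure(out, class = "bn_model")
  validate_cpts(out)
  out
}

# row index into a node's CPT given a named assignment
cpt_row <- function(model, v, assignment) {
  pa <- model$cpts[[v]]$parents
  if (!length(pa)) return(1L)
  pos <- lapply(pa, function(p) match(assignment[[p]], model$dag$nodes[[p]]))
  cards <- vapply(pa, function(p) length(model$dag$nodes[[p]]), 1L)
  cfg_index(pos, cards)
}

#' Joint probability of a full assignment
#'
#' `P(x) = prod_i P(x_i | pa(x_i))`, evaluated by direct CPT lookup; the
#' node order does not matter.
#'
#' @param model A `bn_model`.
#' @param assignment Named character vector or one-row list covering every
#'   node.
#' @return Scalar probability.
#' @export
joint_probability <- function(model, assignment) {
  assignment <- as.list(assignment)
  miss <- setdiff(names(model$dag$nodes), names(assignment))
  if (length(miss))
    stop_tm("assignment misses node(s): %s", paste(miss, collapse = ", "),
            class = "tempmort_domain_error")
  p <- 1
  for (v in names(model$dag$nodes)) {
    s <- match(assignment[[v]], model$dag$nodes[[v]])
    if (is.na(s))
      stop_tm("'%s' is not a state of node '%s'", assignment[[v]], v,
              class = "tempmort_domain_error")
    p <- p * model$cpts[[v]]$prob[cpt_row(model, v, assignment), s]
  }
  unname(p)
}

# full joint by vectorized enumeration: data.frame of states + prob column
enumerate_joint <- function(model) {
  nodes <- model$dag$nodes
  grid <- expand.grid(nodes, stringsAsFactors = FALSE)
  pos <- lapply(names(nodes), function(v) match(grid[[v]], nodes[[v]]))
  names(pos) <- names(nodes)
  p <- rep(1, nrow(grid))
  for (v in names(nodes)) {
    pa <- model$cpts[[v]]$parents
    if (length(pa)) {
      cards <- vapply(pa, function(q) length(nodes[[q]]), 1L)
      rows <- cfg_index(pos[pa], cards)
    } else rows <- rep(1L, nrow(grid))
    p <- p * model$cpts[[v]]$prob[cbind(rows, pos[[v]])]
  }
  grid$prob <- p
  grid
}

#' Marginal conditional probability of a target given one factor
#'
#' `P(target | factor)` obtained by exact enumeration of the network joint:
#' all other variables are summed out and each factor-state row is
#' normalized. A factor state with zero marginal probability yields an
#' `NA` row, flagged in the `undefined` attribute.
#'
#' @param model A `bn_model`.
#' @param target,factor Distinct node names.
#' @param method `"network"` (enumeration of the fitted joint, default) or
#'   `"empirical"` (two-way relative frequencies in `data`).
#' @param data Discrete data frame, required for `method = "empirical"`.
#' @return Matrix: rows = factor states, columns = target states, each
#'   defined row summing to 1.
#' @export
marginal_cpt <- function(model, target, factor,
                         method = c("network", "empirical"), data = NULL) {
  method <- match.arg(method)
  if (identical(target, factor))
    stop_tm("target and factor must be distinct", class = "tempmort_domain_error")
  ts <- model$dag$nodes[[target]]
  fs <- model$dag$nodes[[factor]]
  if (is.null(ts) || is.null(fs))
    stop_tm("unknown node", class = "tempmort_domain_error")
  out <- matrix(NA_real_, length(fs), length(ts), dimnames = list(fs, ts))
  if (method == "network") {
    joint <- enumerate_joint(model)
    for (f in fs) {
      rows <- joint[[factor]] == f
      denom <- sum(joint$prob[rows])
      if (denom > 0)
        out[f, ] <- vapply(ts, function(s)
          sum(joint$prob[rows & joint[[target]] == s]) / denom, 0)
    }
  } else {
    if (is.null(data)) stop_tm("data required for empirical marginal CPT",
                               class = "tempmort_config_error")
    data <- bn_data_factors(model$dag, data)
    tab <- table(data[[factor]], data[[target]])
    rs <- rowSums(tab)
    out[rs > 0, ] <- tab[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  attr(out, "undefined") <- fs[is.na(out[, 1L])]
  out
}

#' Posterior of a target node given evidence, by exact enumeration
#'
#' @param object A `bn_model`.
#' @param target Node to predict.
#' @param evidence Named character vector (possibly empty) of observed
#'   factor states.
#' @param ... Unused.
#' @return List with `posterior` (named probabilities) and `state` (the
#'   argmax; ties broken toward the earliest-listed state of the node,
#'   which for risk nodes is the conservative low-risk label).
#' @export
predict.bn_model <- function(object, target, evidence = character(0), ...) {
  ev <- as.list(evidence)
  bad <- setdiff(names(ev), names(object$dag$nodes))
  if (length(bad))
    stop_tm("unknown evidence node(s): %s", paste(bad, collapse = ", "),
            class = "tempmort_domain_error")
  joint <- enumerate_joint(object)
  keep <- rep(TRUE, nrow(joint))
  for (v in names(ev)) {
    if (!ev[[v]] %in% object$dag$nodes[[v]])
      stop_tm("'%s' is not a state of node '%s'", ev[[v]], v,
              class = "tempmort_domain_error")
    keep <- keep & joint[[v]] == ev[[v]]
  }
  denom <- sum(joint$prob[keep])
  if (denom <= 0)
    stop_tm("evidence has zero probability under the model; posterior undefined",
            class = "tempmort_undefined_posterior")
  ts <- object$dag$nodes[[target]]
  post <- vapply(ts, function(s)
    sum(joint$prob[keep & joint[[target]] == s]) / denom, 0)
  names(post) <- ts
  # which.max takes the first maximum: earliest-listed state wins ties
  list(state = ts[which.max(post)], posterior = post)
}

#' Ancestral sampling from a Bayesian network
#'
#' @param object A `bn_model`.
#' @param nsim Number of rows to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame of factor columns, one row per sample.
#' @export
simulate.bn_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ord <- topo_order(names(object$dag$nodes), object$dag$edges)
  out <- as.data.frame(matrix(NA_character_, nsim, length(ord)),
                       stringsAsFactors = FALSE)
  names(out) <- ord
  for (v in ord) {
    states <- object$dag$nodes[[v]]
    prob <- object$cpts[[v]]$prob
    pa <- object$cpts[[v]]$parents
    if (!length(pa)) {
      out[[v]] <- states[sample.int(length(states), nsim, replace = TRUE,
                                    prob = prob[1L, ])]
    } else {
      pos <- lapply(pa, function(p) match(out[[p]], object$dag$nodes[[p]]))
      cards <- vapply(pa, function(p) length(object$dag$nodes[[p]]), 1L)
      rows <- cfg_index(pos, cards)
      draw <- character(nsim)
      for (r in unique(rows)) {
        idx <- which(rows == r)
        draw[idx] <- states[sample.int(length(states), length(idx),
                                       replace = TRUE, prob = prob[r, ])]
      }
      out[[v]] <- draw
    }
  }
  out[names(object$dag$nodes)]
}

## -------------------------------------------------------- serialization

#' Serialize / deserialize a Bayesian network as JSON
#'
#' CPT arrays are stored row-major over parent configurations with the
#' first parent varying fastest, matching [fit_cpts()].
#'
#' @param model A `bn_model`.
#' @param path File path.
#' @return `bn_from_json` returns a `bn_model`; `bn_to_json` its path,
#'   invisibly.
#' @export
bn_to_json <- function(model, path) {
  obj <- list(
    nodes = model$dag$nodes,
    edges = if (nrow(model$dag$edges))
      apply(model$dag$edges, 1L, as.list, simplify = FALSE) else list(),
    cpts = lapply(model$cpts, function(c)
      list(parents = as.list(c$parents), prob = unname(c$prob)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname bn_to_json
#' @export
bn_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.list(obj$nodes)
  edges <- if (NROW(obj$edges))
    cbind(as.character(obj$edges$from), as.character(obj$edges$to)) else NULL
  cpts <- lapply(obj$cpts, function(c) {
    p <- c$prob
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    p
  })
  bn_model(nodes, edges, cpts)
}

#' Export a DAG in Graphviz DOT format
#'
#' @param dag A `bn_dag` (or `bn_model`, whose graph is used).
#' @param path Optional file; if `NULL` the DOT text is returned.
#' @return DOT source as a character scalar (invisibly when written).
#' @export
dag_to_dot <- function(dag, path = NULL) {
  if (inherits(dag, "bn_model")) dag <- dag$dag
  lines <- c("digraph bn {",
             paste0("  \"", names(dag$nodes), "\";"),
             if (nrow(dag$edges))
               paste0("  \"", dag$edges[, 1L], "\" -> \"",
                      dag$edges[, 2L], "\";"),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
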