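# shared fixtures, all generated in code

# one-region daily series drawn straight from a single synthetic station
one_region_series <- function(seed, ...) {
  cfg <- world_config(n_regions = 1L, n_stations = 1L, seed = seed,
                      station_offset_sd = 0, ...)
  obs <- tempmort:::station_obs_table(generate_stations(cfg))
  series <- data.frame(region_id = "R01", date = obs$date, tmean = obs$tmean,
                       tmax = obs$tmax, tmin = obs$tmin, rh = obs$rh)
  list(cfg = cfg, series = series)
}

one_region_with_deaths <- function(seed, ...) {
  w <- one_region_series(seed, ...)
  w$series <- generate_mortality(w$series, w$cfg, label = "R01")
  w
}

# strongly dependent 3-node chain A -> B -> C
chain_model <- function() {
  bn_model(list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1")),
           rbind(c("A", "B"), c("B", "C")),
           list(A = c(0.4, 0.6),
                B = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                C = rbind(c(0.85, 0.15), c(0.1, 0.9))))
}

# two-node toy with known joint
two_node_model <- function() {
  bn_model(list(a = c("a1", "a2"), b = c("b1", "b2")), rbind(c("a", "b")),
           list(a = c(0.6, 0.4), b = rbind(c(0.5, 0.5), c(0.3, 0.7))))
}

# 4-node model with a collider, 2 states each (16 joint states -> subsets
# used where <= 12 total states are needed)
collider_model <- function() {
  bn_model(list(a = c("0", "1"), b = c("0", "1"), c = c("0", "1"),
                d = c("0", "1")),
           rbind(c("a", "c"), c("b", "c"), c("c", "d")),
           list(a = c(0.3, 0.7), b = c(0.6, 0.4),
                c = rbind(c(0.9, 0.1), c(0.5, 0.5),
                          c(0.4, 0.6), c(0.05, 0.95)),
                d = rbind(c(0.8, 0.2), c(0.25, 0.75))))
}

# independent oracle: full joint of a bn_model by explicit recursive
# factorization over a state grid, touching none of the package's
# enumeration helpers beyond the raw CPT matrices
oracle_joint <- function(model) {
  nodes <- model$dag$nodes
  grid <- expand.grid(nodes, stringsAsFactors = FALSE)
  prob <- vapply(seq_len(nrow(grid)), function(i) {
    p <- 1
    for (v in names(nodes)) {
      cpt <- model$cpts[[v]]
      row <- 1L
      mult <- 1L
      for (pa in cpt$parents) {
        row <- row + (match(grid[[pa]][i], nodes[[pa]]) - 1L) * mult
        mult <- mult * length(nodes[[pa]])
      }
      p <- p * cpt$prob[row, match(grid[[v]][i], nodes[[v]])]
    }
    p
  }, 0)
  grid$prob <- prob
  grid
}

# exhaustive single-cut information gain oracle over all midpoints
# between adjacent distinct values
oracle_best_single_cut <- function(x, labels) {
  ent <- function(l) {
    n <- length(l)
    if (!n) return(0)
    p <- table(l) / n
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  u <- sort(unique(x))
  cand <- (u[-length(u)] + u[-1L]) / 2
  went <- vapply(cand, function(c) {
    l <- x < c
    (sum(l) * ent(labels[l]) + sum(!l) * ent(labels[!l])) / length(x)
  }, 0)
  cand[which.min(went)]
}
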