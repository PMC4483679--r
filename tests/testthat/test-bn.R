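test_that("DAG construction rejects cycles, self-loops and duplicates", {
  nodes <- list(a = c("0", "1"), b = c("0", "1"), c = c("0", "1"))
  expect_s3_class(dag(nodes, rbind(c("a", "b"), c("b", "c"))), "bn_dag")
  expect_error(dag(nodes, rbind(c("a", "b"), c("b", "a"))),
               class = "tempmort_invalid_dag")
  expect_error(dag(nodes, rbind(c("a", "a"))), class = "tempmort_invalid_dag")
  expect_error(dag(nodes, rbind(c("a", "b"), c("a", "b"))),
               class = "tempmort_invalid_dag")
  expect_error(dag(nodes, rbind(c("a", "z"))), class = "tempmort_invalid_dag")
})

test_that("BIC matches the hand-computed multinomial likelihood", {
  d <- data.frame(x = c(rep("1", 6), rep("0", 4)))
  g <- empty_dag(list(x = c("0", "1")))
  expected <- 6 * log(0.6) + 4 * log(0.4) - log(10) / 2
  expect_equal(bic_score(g, d), expected)
})

test_that("BIC decomposes into per-node terms", {
  m <- collider_model()
  d <- simulate(m, 300, seed = 3)
  g <- m$dag
  total <- bic_score(g, d)
  # independent per-node recomputation
  n <- nrow(d)
  acc <- 0
  for (v in names(g$nodes)) {
    pa <- g$edges[g$edges[, 2] == v, 1]
    dd <- d
    for (w in names(g$nodes)) dd[[w]] <- factor(dd[[w]], levels = g$nodes[[w]])
    if (length(pa) == 0) {
      cnt <- table(dd[[v]])
      ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0] / n))
      q <- 1
    } else {
      cfg <- interaction(dd[pa], drop = FALSE)
      tab <- table(cfg, dd[[v]])
      ll <- 0
      for (r in seq_len(nrow(tab))) for (s in seq_len(ncol(tab)))
        if (tab[r, s] > 0)
          ll <- ll + tab[r, s] * log(tab[r, s] / sum(tab[r, ]))
      q <- nlevels(cfg)
    }
    acc <- acc + ll - log(n) / 2 * (length(g$nodes[[v]]) - 1) * q
  }
  expect_equal(total, acc)
})

test_that("BIC is invariant to state relabeling", {
  m <- chain_model()
  d <- simulate(m, 500, seed = 5)
  g <- m$dag
  score1 <- bic_score(g, d)
  d2 <- d
  d2$B <- c("0" = "yes", "1" = "no")[d2$B]
  g2 <- dag(list(A = c("0", "1"), B = c("yes", "no"), C = c("0", "1")),
            g$edges)
  expect_equal(bic_score(g2, d2), score1)
})

test_that("an edge between independent variables lowers BIC", {
  set.seed(11)
  worse <- 0L
  for (i in 1:20) {
    d <- data.frame(a = sample(c("0", "1"), 5000, TRUE),
                    b = sample(c("0", "1"), 5000, TRUE))
    nodes <- list(a = c("0", "1"), b = c("0", "1"))
    worse <- worse + (bic_score(dag(nodes, rbind(c("a", "b"))), d) <
                        bic_score(empty_dag(nodes), d))
  }
  expect_gte(worse / 20, 0.95)
})

test_that("SA search recovers the chain's equivalence class and never regresses", {
  truth <- chain_model()
  d <- simulate(truth, 5000, seed = 11)
  sched <- sa_schedule(cooling = 0.95, moves_per_temp = 10, max_iter = 2000)
  hits <- 0L
  for (s in 1:20) {
    g <- sa_search(d, sched, seed = s)
    hits <- hits + same_equivalence_class(g, truth$dag)
    expect_gte(attr(g, "score"), bic_score(empty_dag(g$nodes), d))
  }
  expect_gte(hits / 20, 0.9)
})

test_that("a zero-iteration schedule returns the initial graph", {
  d <- simulate(chain_model(), 100, seed = 2)
  g <- sa_search(d, sa_schedule(max_iter = 0), seed = 1)
  expect_equal(nrow(g$edges), 0L)
})

test_that("blacklists and whitelists constrain the search", {
  truth <- chain_model()
  d <- simulate(truth, 2000, seed = 13)
  sched <- sa_schedule(cooling = 0.9, moves_per_temp = 10, max_iter = 500)
  bl <- rbind(c("A", "B"), c("B", "A"))
  g <- sa_search(d, sched, seed = 3, blacklist = bl)
  expect_false(any(g$edges[, 1] == "A" & g$edges[, 2] == "B"))
  expect_false(any(g$edges[, 1] == "B" & g$edges[, 2] == "A"))
  wl <- rbind(c("C", "A"))
  g2 <- sa_search(d, sched, seed = 3, whitelist = wl)
  expect_true(any(g2$edges[, 1] == "C" & g2$edges[, 2] == "A"))
})

test_that("CPT estimation applies smoothing arithmetic exactly", {
  g <- empty_dag(list(x = c("0", "1")))
  d <- data.frame(x = c("1", "1", "1", "0"))
  expect_equal(unname(fit_cpts(g, d, smoothing = 0)$cpts$x$prob[1, "1"]), 0.75)
  expect_equal(unname(fit_cpts(g, d, smoothing = 1)$cpts$x$prob[1, "1"]), 4 / 6)
  # unseen parent configuration -> uniform row at MLE
  g2 <- dag(list(p = c("0", "1"), c = c("0", "1")), rbind(c("p", "c")))
  d2 <- data.frame(p = c("0", "0"), c = c("0", "1"))
  m2 <- fit_cpts(g2, d2, smoothing = 0)
  expect_equal(unname(m2$cpts$c$prob["1", ]), c(0.5, 0.5))
})

test_that("CPT rows sum to one on fuzzed DAGs and data", {
  set.seed(17)
  for (i in 1:100) {
    nn <- sample(2:4, 1)
    nodes <- stats::setNames(
      lapply(seq_len(nn), function(k) as.character(seq_len(sample(2:3, 1)))),
      letters[seq_len(nn)])
    edges <- NULL
    for (a in seq_len(nn - 1)) for (b in (a + 1):nn)
      if (runif(1) < 0.4) edges <- rbind(edges, c(letters[a], letters[b]))
    g <- dag(nodes, edges)
    d <- as.data.frame(lapply(nodes, function(st)
      sample(st, 30, TRUE)), stringsAsFactors = FALSE)
    m <- fit_cpts(g, d, smoothing = sample(0:2, 1))
    for (v in names(m$cpts))
      expect_true(all(abs(rowSums(m$cpts[[v]]$prob) - 1) < 1e-9))
  }
})

test_that("round-trip CPT estimation recovers a known model", {
  truth <- chain_model()
  d <- simulate(truth, 50000, seed = 19)
  m <- fit_cpts(truth$dag, d, smoothing = 0)
  for (v in names(m$cpts))
    expect_lt(max(abs(m$cpts[[v]]$prob - truth$cpts[[v]]$prob)), 0.01)
})

test_that("joint probabilities multiply CPT entries in any order", {
  m <- two_node_model()
  expect_equal(joint_probability(m, c(a = "a1", b = "b1")), 0.3)
  expect_equal(joint_probability(m, c(b = "b1", a = "a1")), 0.3)
  expect_error(joint_probability(m, c(a = "a1")),
               class = "tempmort_domain_error")
  expect_error(joint_probability(m, c(a = "bogus", b = "b1")),
               class = "tempmort_domain_error")
})

test_that("enumeration inference matches an independent oracle", {
  for (m in list(two_node_model(), chain_model(), collider_model())) {
    oj <- oracle_joint(m)
    expect_equal(sum(oj$prob), 1, tolerance = 1e-12)
    # joint_probability on every full assignment
    for (i in seq_len(nrow(oj))) {
      a <- unlist(oj[i, names(m$dag$nodes)])
      expect_equal(joint_probability(m, a), oj$prob[i], tolerance = 1e-12)
    }
    nodes <- names(m$dag$nodes)
    tgt <- nodes[length(nodes)]
    fac <- nodes[1]
    mc <- marginal_cpt(m, tgt, fac)
    expect_true(all(abs(rowSums(mc) - 1) < 1e-9))
    for (f in m$dag$nodes[[fac]]) {
      rows <- oj[[fac]] == f
      for (s in m$dag$nodes[[tgt]]) {
        want <- sum(oj$prob[rows & oj[[tgt]] == s]) / sum(oj$prob[rows])
        expect_equal(mc[f, s], want, tolerance = 1e-12)
      }
    }
    # posterior under evidence vs oracle conditional
    ev <- stats::setNames(m$dag$nodes[[fac]][1], fac)
    pr <- predict(m, tgt, ev)
    rows <- oj[[fac]] == ev[[fac]]
    for (s in m$dag$nodes[[tgt]])
      expect_equal(unname(pr$posterior[s]),
                   sum(oj$prob[rows & oj[[tgt]] == s]) / sum(oj$prob[rows]),
                   tolerance = 1e-12)
  }
})

test_that("marginal CPT collapses to the learned CPT for a lone parent", {
  m <- two_node_model()
  mc <- marginal_cpt(m, "b", "a")
  attr(mc, "undefined") <- NULL
  expect_equal(unname(mc), unname(m$cpts$b$prob))
  # independence: rows identical when target ignores the factor
  ind <- bn_model(list(a = c("0", "1"), b = c("0", "1")), NULL,
                  list(a = c(0.3, 0.7), b = c(0.25, 0.75)))
  mci <- marginal_cpt(ind, "b", "a")
  expect_equal(mci["0", ], mci["1", ])
})

test_that("empirical marginal CPTs use two-way frequencies", {
  m <- chain_model()
  d <- simulate(m, 2000, seed = 23)
  mc <- marginal_cpt(m, "B", "A", method = "empirical", data = d)
  tab <- table(d$A, d$B)
  expect_equal(unname(mc["1", "1"]), unname(tab["1", "1"] / sum(tab["1", ])))
})

test_that("prediction handles no evidence, full parents, ties and contradictions", {
  m <- chain_model()
  # no evidence: the prior marginal of the target
  pr <- predict(m, "C")
  oj <- oracle_joint(m)
  expect_equal(unname(pr$posterior["1"]),
               sum(oj$prob[oj$C == "1"]), tolerance = 1e-12)
  # evidence = the target's full parent configuration returns the CPT row
  pr2 <- predict(m, "C", c(B = "1"))
  expect_equal(unname(pr2$posterior), unname(m$cpts$C$prob["1", ]))
  # exact tie breaks toward the first-listed state
  tie <- bn_model(list(risk = c("low_risk", "high_risk")), NULL,
                  list(risk = c(0.5, 0.5)))
  expect_equal(predict(tie, "risk")$state, "low_risk")
  # contradictory evidence
  z <- bn_model(list(a = c("0", "1"), b = c("0", "1")), rbind(c("a", "b")),
                list(a = c(1, 0), b = rbind(c(1, 0), c(0, 1))))
  expect_error(predict(z, "b", c(a = "1")),
               class = "tempmort_undefined_posterior")
})

test_that("models serialize to JSON and DOT", {
  m <- collider_model()
  tf <- withr::local_tempfile(fileext = ".json")
  bn_to_json(m, tf)
  back <- bn_from_json(tf)
  expect_equal(back$dag$nodes, m$dag$nodes)
  expect_setequal(paste(back$dag$edges[, 1], back$dag$edges[, 2]),
                  paste(m$dag$edges[, 1], m$dag$edges[, 2]))
  for (v in names(m$cpts))
    expect_equal(unname(back$cpts[[v]]$prob), unname(m$cpts[[v]]$prob))
  dot <- dag_to_dot(m)
  expect_match(dot, "\"a\" -> \"c\"", fixed = TRUE)
})
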