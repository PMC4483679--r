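test_that("a perfectly separable factor gets its unique cut in the gap", {
  cuts <- supervised_splits(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_length(cuts, 1L)
  expect_gt(cuts, 3)
  expect_lt(cuts, 10)
  expect_false(isTRUE(attr(cuts, "fallback")))
})

test_that("label-independent factors fall back to a median cut", {
  set.seed(21)
  rejected <- 0L
  for (i in 1:20) {
    x <- rnorm(40)
    l <- sample(rep(0:1, 20))
    cuts <- supervised_splits(x, l)
    if (isTRUE(attr(cuts, "fallback"))) {
      rejected <- rejected + 1L
      expect_equal(as.numeric(cuts), median(x))
    }
  }
  # MDL should reject essentially every permuted labelling
  expect_gte(rejected, 18L)
})

test_that("the accepted top-level cut matches exhaustive info-gain search", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(8:20, 1)
    x <- round(runif(n, 0, 10), 1)
    if (length(unique(x)) < 2) next
    l <- as.integer(x + rnorm(n) > 5)
    if (length(unique(l)) < 2) next
    best <- oracle_best_single_cut(x, l)
    cuts <- supervised_splits(x, l)
    if (isTRUE(attr(cuts, "fallback"))) next
    # the recursion's first (highest-gain) split must induce the same
    # partition as the oracle's best single cut
    expect_true(any(vapply(cuts, function(c)
      identical(x < c, x < best), TRUE)),
      info = sprintf("case %d: oracle %.3f vs cuts %s", i, best,
                     paste(round(cuts, 3), collapse = ",")))
  }
})

test_that("splits are invariant to strictly increasing transformations", {
  set.seed(41)
  x <- runif(30, 1, 9)
  l <- as.integer(x > 4)
  l[sample(30, 3)] <- 1 - l[sample(30, 3)]
  c1 <- supervised_splits(x, l)
  c2 <- supervised_splits(exp(x), l)
  # the induced partitions agree even though the cut values differ
  expect_equal(length(c1), length(c2))
  for (k in seq_along(c1))
    expect_equal(x < sort(c1)[k], exp(x) < sort(c2)[k])
})

test_that("degenerate inputs are rejected", {
  expect_error(supervised_splits(1:6, rep(1, 6)),
               class = "tempmort_degenerate_labels")
  expect_error(supervised_splits(rep(2, 6), rep(0:1, 3)),
               class = "tempmort_data_error")
})

test_that("scheme application honors the boundary-to-upper convention", {
  sch <- build_scheme(
    data.frame(region_id = c("R1", "R2"), pct_industry = c(5, 25)),
    labels = factor(c("low_risk", "high_risk")),
    manual = list(pct_industry = c(6.36, 23.14)))
  d <- apply_scheme(data.frame(region_id = c("R1", "R2", "R3"),
                               pct_industry = c(5.0, 23.14, 30)), sch)
  expect_equal(as.character(d$pct_industry), c("low", "high", "high"))
  expect_true(is.ordered(d$pct_industry))
})

test_that("manual printed intervals keep their bracket semantics", {
  mi <- manual_intervals(c("[1.02, 6.36]", "(6.36, 23.14]", "(23.14, 51.24)"))
  sch <- build_scheme(data.frame(region_id = "R1", pct_industry = 10),
                      labels = factor(c("low_risk", "high_risk"),
                                      levels = c("low_risk", "high_risk")),
                      manual = list(pct_industry = mi))
  vals <- data.frame(region_id = sprintf("R%d", 1:4),
                     pct_industry = c(6.36, 23.14, 23.15, 5))
  expect_warning(d <- apply_scheme(
    data.frame(region_id = "R0", pct_industry = 60), sch), "outside")
  d <- apply_scheme(vals, sch)
  # right-closed printed brackets: boundary values stay in the lower state
  expect_equal(as.character(d$pct_industry),
               c("low", "middle", "high", "low"))
})

test_that("an empty cut list maps every region to one state", {
  sch <- structure(list(x = list(type = "numeric", cuts = numeric(0),
                                 right_closed = logical(0), states = "all")),
                   class = "tm_scheme")
  d <- apply_scheme(data.frame(region_id = c("a", "b"), x = c(-5, 100)), sch)
  expect_equal(as.character(d$x), c("all", "all"))
})

test_that("state counts after discretization match a brute-force histogram", {
  set.seed(51)
  x <- runif(200, 0, 50)
  cuts <- c(10, 30)
  sch <- structure(list(x = list(type = "numeric", cuts = cuts,
                                 right_closed = c(FALSE, FALSE),
                                 states = c("low", "middle", "high"))),
                   class = "tm_scheme")
  d <- apply_scheme(data.frame(region_id = seq_along(x), x = x), sch)
  expect_equal(as.vector(table(d$x)),
               c(sum(x < 10), sum(x >= 10 & x < 30), sum(x >= 30)))
})

test_that("risk labelling applies the 1% cold and 10% heat thresholds", {
  expect_equal(as.character(label_risk(12, "heat")), "high_risk")
  expect_equal(as.character(label_risk(10, "heat")), "high_risk")
  expect_equal(as.character(label_risk(9.999, "heat")), "low_risk")
  expect_equal(as.character(label_risk(0.5, "cold")), "low_risk")
  expect_equal(as.character(label_risk(1, "cold")), "high_risk")
  expect_error(label_risk(5, "warm"), class = "tempmort_domain_error")
  # monotone: raising the percent change never flips high -> low
  pc <- sort(runif(30, 0, 20))
  lab <- label_risk(pc, "heat")
  expect_true(all(diff(as.integer(lab)) >= 0))
})

test_that("schemes serialize to JSON and back", {
  sch <- build_scheme(
    data.frame(region_id = c("R1", "R2", "R3", "R4"),
               beds = c(10, 20, 40, 50),
               zone = c("a", "a", "b", "b")),
    labels = factor(c("low_risk", "low_risk", "high_risk", "high_risk")))
  tf <- withr::local_tempfile(fileext = ".json")
  write_scheme_json(sch, tf)
  back <- read_scheme_json(tf)
  expect_equal(back$beds$cuts, sch$beds$cuts)
  expect_equal(back$zone$states, sch$zone$states)
})

test_that("training tables join labels onto discrete factors by region", {
  disc <- data.frame(region_id = c("R1", "R2"),
                     beds = factor(c("low", "high")))
  eff <- data.frame(region_id = c("R1", "R2"), side = "heat",
                    percent_change = c(15, 2))
  tt <- make_training_table(disc, eff, "heat")
  expect_equal(rownames(tt), c("R1", "R2"))
  expect_equal(as.character(tt$risk), c("high_risk", "low_risk"))
  expect_false("percent_change" %in% names(tt))
})
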