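sgt_flat <- function(costs) {
  testing_strategy("sgt", "sequential", paste0("g", seq_along(costs)),
                   costs)
}

test_that("percent change matches hand arithmetic and is reciprocal", {
  expect_equal(percent_change(68.26, 1048.32), 1435.78, tolerance = 0.005)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(17.5, 231.5), 1222.857, tolerance = 1e-3)
  expect_equal(percent_change(2232, 1090), -51.165, tolerance = 1e-3)
  expect_error(percent_change(0, 10), "old = 0")
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 1, 1000); b <- runif(1, 1, 1000)
    p_ab <- percent_change(a, b); p_ba <- percent_change(b, a)
    expect_equal((1 + p_ab / 100) * (1 + p_ba / 100), 1,
                 tolerance = 1e-9)
  }
})

test_that("cumulative single-gene cost sums the first k steps", {
  s <- sgt_flat(rep(30, 4))
  expect_equal(sgt_cumulative_cost(s, 2), 60)
  expect_equal(sgt_cumulative_cost(s, 1), 30)
  s2 <- sgt_flat(c(68.26, 198.06, 198.06))
  expect_equal(sgt_cumulative_cost(s2, 3), 464.38)
  expect_error(sgt_cumulative_cost(s, 5), "out of range")
  expect_error(sgt_cumulative_cost(s, 0), "out of range")
  # monotone non-decreasing in k
  set.seed(5)
  costs <- runif(8, 0, 300)
  s3 <- sgt_flat(costs)
  cum <- vapply(1:8, function(k) sgt_cumulative_cost(s3, k), numeric(1))
  expect_true(all(diff(cum) >= 0))
})

test_that("break-even matches an enumeration oracle, ties included", {
  expect_equal(break_even_biomarker(100, sgt_flat(rep(30, 4))), 4L)
  expect_equal(break_even_biomarker(0, sgt_flat(rep(30, 4))), 1L)
  expect_identical(break_even_biomarker(1000, sgt_flat(rep(100, 5))),
                   NA_integer_)
  expect_equal(break_even_biomarker(60, sgt_flat(rep(30, 4))), 2L)  # tie
  set.seed(9)
  for (i in 1:30) {
    costs <- round(runif(sample(1:8, 1), 0, 200), 2)
    panel <- round(runif(1, 0, 900), 2)
    s <- sgt_flat(costs)
    # independent oracle: scan k explicitly
    oracle <- NA_integer_
    for (k in seq_along(costs)) {
      if (sum(costs[1:k]) >= panel) { oracle <- k; break }
    }
    expect_identical(break_even_biomarker(panel, s), oracle)
  }
  # non-increasing as the panel gets cheaper
  s <- sgt_flat(c(50, 80, 20, 120))
  be <- vapply(c(270, 150, 140, 60, 10, 0), function(p) {
    break_even_biomarker(p, s)
  }, integer(1))
  expect_true(all(diff(be) <= 0))
})

test_that("hands-on hours scale minutes across the cohort", {
  panel <- testing_strategy("ngs", "panel", "all", 1048.32,
                            minutes = c(technician = 5, biologist = 20,
                                        physician = 20))
  h <- hands_on_totals(210, panel)
  expect_equal(h[["technician"]], 17.5)
  expect_equal(h[["biologist"]], 70)
  expect_equal(h[["physician"]], 70)
  expect_equal(unname(hands_on_totals(0, panel)), c(0, 0, 0))
  seqs <- testing_strategy("sgt", "sequential", c("a", "b"), c(10, 10),
                           minutes = list(c(technician = 30),
                                          c(technician = 30,
                                            biologist = 10)))
  expect_equal(hands_on_totals(60, seqs)[["technician"]], 60)
})

test_that("cohort testing cost and cost per qualifying case floor at presentation", {
  expect_equal(euro_floor(cohort_testing_cost(164, 1048.32)), 171924)
  expect_equal(cohort_testing_cost(0, 1048.32), 0)
  expect_equal(euro_floor(cohort_testing_cost(210, 1048.32)), 220147)
  expect_equal(euro_floor(cost_per_qualifying_case(171924, 77)), 2232)
  expect_equal(euro_floor(cost_per_qualifying_case(171924, 51)), 3371)
  expect_true(is.na(cost_per_qualifying_case(171924, 0)))
})

test_that("qualifying counts behind the printed per-variant costs are recoverable", {
  # brute-force the integer count that best matches each printed ratio
  best_n <- function(total, per) {
    which.min(vapply(1:200, function(n) abs(total / n - per), numeric(1)))
  }
  expect_equal(best_n(171924, 2232), 77)
  expect_equal(best_n(171924, 3371), 51)
})

test_that("cohort strategy costs are additive and honour early stopping", {
  cohort <- data.frame(
    gene = c("EGFR", "ALK", "WT", "RET"),
    escat_tier = c("I", "I", NA, "I"), stringsAsFactors = FALSE)
  sgt <- testing_strategy("sgt", "sequential", c("EGFR", "KRAS", "ALK"),
                          c(100, 100, 50))
  full <- cohort_strategy_costs(cohort, sgt)
  expect_equal(full, rep(250, 4))
  early <- cohort_strategy_costs(cohort, sgt,
                                 stop_on_first_positive = TRUE)
  # EGFR stops at step 1, ALK at step 3, WT and off-sequence RET run all
  expect_equal(early, c(100, 250, 250, 250))
  panel <- testing_strategy("ngs", "panel", c("EGFR", "KRAS", "ALK"), 180)
  res <- compare_strategies(cohort, panel, sgt)
  expect_equal(res$panel$total, sum(cohort_strategy_costs(cohort, panel)))
  expect_equal(res$sgt$total, 1000)
  expect_equal(res$n_qualifying, 3)
  expect_equal(res$panel$cost_per_qualifying_variant, 720 / 3)
  expect_equal(res$break_even, 2L)
})
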