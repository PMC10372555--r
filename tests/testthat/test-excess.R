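pred_frame <- function() {
  months <- month_seq("2016-01", "2016-06")
  expand.grid(variable = "maize", lga_id = c("lga1", "lga2"),
              month = months, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)[, c("variable", "lga_id", "month")]
}

test_that("scenario rules substitute the prescribed reference values", {
  fr <- pred_frame()
  fr <- fr[order(fr$lga_id, fr$month), ]
  fr$value <- rep(c(0.20, 0.20, 0.20, 0.30, 0.30, 0.30), 2)
  ml <- scenario_spec("most_likely",
                      list(maize = list(type = "window_mean",
                                        months = c("2016-01", "2016-02", "2016-03",
                                                   "2016-04", "2016-05", "2016-06"))),
                      displacement_retention = 0.05)
  out <- build_scenario_data(fr, ml)
  expect_equal(out$value, rep(0.25, 12)) # mean of the two reference blocks
  # best case: the series minimum per LGA
  best <- scenario_spec("reasonable_best",
                        list(maize = list(type = "series_min")), 0)
  expect_equal(build_scenario_data(fr, best)$value, rep(0.20, 12))
  # baseline: mean of the first k months
  base <- scenario_spec("x", list(maize = list(type = "baseline", k = 2)), 1)
  expect_equal(build_scenario_data(fr, base)$value, rep(0.20, 12))
  # missing reference months are a configuration error
  bad <- scenario_spec("y", list(maize = list(type = "window_mean",
                                              months = "2015-01")), 1)
  expect_error(build_scenario_data(fr, bad), "2015-01")
  expect_error(scenario_spec("z", list(maize = list(type = "nope"))), "nope")
  expect_error(scenario_spec("z", list(), displacement_retention = 2), "retention")
})

test_that("degenerate bootstrap (s = 0) reproduces the closed form exactly", {
  bt <- bootstrap_tolls(m = log(0.5), s = 0, person_days = 3e6, n = 1000)
  expect_true(all(bt$draws == 150))
  expect_equal(bt$summary$point, 150)
  expect_equal(bt$summary$ci_low, 150)
  expect_equal(bt$summary$ci_high, 150)
})

test_that("bootstrap quantiles match lognormal closed forms at large n", {
  m <- log(0.8); s <- 0.25; pd <- 2e6
  bt <- bootstrap_tolls(m, s, pd, n = 1e5, seed = 42)
  scale <- pd / 1e4
  expect_equal(bt$summary$point, exp(m) * scale, tolerance = 0.01)
  expect_equal(bt$summary$ci_low, exp(m + qnorm(0.025) * s) * scale,
               tolerance = 0.02)
  expect_equal(bt$summary$ci_high, exp(m + qnorm(0.975) * s) * scale,
               tolerance = 0.02)
  expect_true(bt$summary$ci_low <= bt$summary$point)
  expect_true(bt$summary$point <= bt$summary$ci_high)
})

test_that("bootstrap is seeded and supports paired draws", {
  a <- bootstrap_tolls(c(0, 1), c(0.2, 0.3), c(1e5, 2e5), n = 500, seed = 9)
  b <- bootstrap_tolls(c(0, 1), c(0.2, 0.3), c(1e5, 2e5), n = 500, seed = 9)
  expect_identical(a$draws, b$draws)
  set.seed(1)
  z <- matrix(rnorm(2 * 500), 2)
  p1 <- bootstrap_tolls(c(0, 1), c(0.2, 0.3), c(1e5, 2e5), n = 500, z = z)
  p2 <- bootstrap_tolls(c(0.1, 1.1), c(0.2, 0.3), c(1e5, 2e5), n = 500, z = z)
  # common random numbers: the log-draw difference is exactly the m shift
  expect_equal(log(p2$draws) - log(p1$draws),
               matrix(0.1, 2, 500), tolerance = 1e-12)
})

test_that("aggregation sums draw-wise and rounds at report time only", {
  set.seed(33)
  bt <- bootstrap_tolls(m = rnorm(6, 0, 0.1), s = rep(0.2, 6),
                        person_days = rep(1e6, 6), n = 400, seed = 3)
  grp <- c("A", "A", "B", "B", "B", "A")
  agg <- aggregate_draws(bt, grp)
  expect_equal(agg$draws["A", ], colSums(bt$draws[grp == "A", ]))
  expect_equal(agg$draws["B", ], colSums(bt$draws[grp == "B", ]))
  # with s = 0 the group point estimate is the exact sum of stratum tolls
  bt0 <- bootstrap_tolls(m = log(c(1, 2, 0.5)), s = rep(0, 3),
                         person_days = c(1e6, 2e6, 4e6), n = 100)
  agg0 <- aggregate_draws(bt0, rep("all", 3))
  expect_equal(agg0$summary$point, sum(exp(log(c(1, 2, 0.5))) * c(1e6, 2e6, 4e6) / 1e4))
  expect_equal(round_toll(908149), 908100)
})

test_that("identical scenarios give excess exactly zero for every group", {
  bt <- bootstrap_tolls(m = rnorm(4), s = rep(0.3, 4),
                        person_days = rep(5e5, 4), n = 300, seed = 5)
  grp <- c("A", "A", "B", "B")
  ex <- excess_from_draws(aggregate_draws(bt, grp), aggregate_draws(bt, grp))
  expect_true(all(ex$draws == 0))
  expect_equal(ex$summary$point, c(0, 0))
  expect_equal(ex$summary$ci_low, c(0, 0))
  expect_equal(ex$summary$ci_high, c(0, 0))
  # unpaired inputs are rejected
  other <- bootstrap_tolls(m = rnorm(3), s = rep(0.3, 3),
                           person_days = rep(5e5, 3), n = 300, seed = 5)
  expect_error(excess_from_draws(bt, other), "paired")
})

test_that("negative excess arises when the counterfactual exceeds observed", {
  obs <- bootstrap_tolls(m = log(0.5), s = 0, person_days = 1e6, n = 100)
  cf <- bootstrap_tolls(m = log(0.8), s = 0, person_days = 1e6, n = 100)
  ex <- excess_from_draws(obs, cf)
  expect_lt(ex$summary$point, 0)
})

test_that("monotone scenario response under a positive coefficient", {
  # higher counterfactual maize level -> higher counterfactual toll ->
  # lower excess, for a model with a positive maize coefficient
  mdl <- structure(list(beta = c("(Intercept)" = log(0.5e-4), maize = 0.9),
                        cov_beta = diag(c(0.01, 0.01)),
                        term_labels = "maize", xlevels = list(),
                        u_hat = NULL, phi_scale = 1),
                   class = "rate_model")
  pd <- rep(1e6, 4)
  z <- matrix(rnorm(4 * 300), 4)
  toll_at <- function(level) {
    pr <- predict_stratum(mdl, data.frame(maize = rep(level, 4)))
    aggregate_draws(bootstrap_tolls(pr$m, pr$s, pd, n = 300, z = z),
                    rep("all", 4))$summary$point
  }
  lvls <- c(0.1, 0.3, 0.5)
  tolls <- vapply(lvls, toll_at, numeric(1))
  expect_true(all(diff(tolls) > 0))
})

test_that("period rates reproduce the toll/person-time identity draw-wise", {
  bt <- bootstrap_tolls(m = log(c(0.4, 0.9)), s = c(0.2, 0.1),
                        person_days = c(1e6, 3e6), n = 200, seed = 11)
  r <- rate_from_draws(bt)
  expect_equal(r$point, median(1e4 * colSums(bt$draws) / 4e6))
  expect_equal(r$ci_low, unname(quantile(1e4 * colSums(bt$draws) / 4e6, 0.025)))
})
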