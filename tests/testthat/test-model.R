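test_that("intercept-only quasi-Poisson fit matches closed forms", {
  m <- fit_quasipoisson(c(1, 0, 3), c(100, 200, 100))
  expect_equal(unname(m$beta), log(4 / 400), tolerance = 1e-7)
  expect_equal(unname(round(m$beta, 4)), -4.6052)
  # Pearson dispersion by hand: [(1-1)^2/1 + (0-2)^2/2 + (3-1)^2/1] / 2 = 3
  expect_equal(m$phi, 3.0, tolerance = 1e-8)
})

test_that("two-group saturated fit recovers the exact rate ratio", {
  d <- data.frame(g = factor(c("a", "a", "b", "b")))
  m <- fit_quasipoisson(c(5, 5, 10, 10), rep(1000, 4), data = d, terms = "g")
  expect_equal(unname(m$beta["gb"]), log(2), tolerance = 1e-9)
  expect_equal(unname(m$beta["(Intercept)"]), log(10 / 2000), tolerance = 1e-9)
})

test_that("coefficients agree with an independent IRLS oracle", {
  set.seed(201)
  n <- 200
  X <- cbind(1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  pt <- runif(n, 200, 2000)
  off <- log(pt)
  beta_true <- c(-6, 0.4, -0.7)
  y <- rpois(n, exp(drop(X %*% beta_true) + off))
  w <- runif(n, 0.3, 1)
  m <- fit_quasipoisson(y, pt, data = data.frame(x1 = X[, 2], x2 = X[, 3]),
                        terms = c("x1", "x2"), weights = w)
  oracle <- irls_poisson(X, y, off, w)
  expect_equal(unname(m$beta), unname(oracle), tolerance = 1e-6)
})

test_that("offset semantics: doubling person-time shifts only the intercept", {
  set.seed(7)
  d <- data.frame(x = rnorm(50))
  pt <- runif(50, 100, 1000)
  y <- rpois(50, exp(-5 + 0.5 * d$x) * pt)
  m1 <- fit_quasipoisson(y, pt, data = d, terms = "x")
  m2 <- fit_quasipoisson(y, 2 * pt, data = d, terms = "x")
  expect_equal(unname(m2$beta["(Intercept)"]),
               unname(m1$beta["(Intercept)"]) - log(2), tolerance = 1e-8)
  expect_equal(unname(m2$beta["x"]), unname(m1$beta["x"]), tolerance = 1e-8)
})

test_that("zero robustness weight is equivalent to deleting the households", {
  set.seed(15)
  d <- data.frame(x = rnorm(60))
  pt <- runif(60, 100, 1000)
  y <- rpois(60, exp(-5 + 0.3 * d$x) * pt)
  drop_idx <- 41:60
  w <- rep(1, 60)
  w[drop_idx] <- 0
  m_w <- fit_quasipoisson(y, pt, data = d, terms = "x", weights = w)
  m_d <- fit_quasipoisson(y[-drop_idx], pt[-drop_idx],
                          data = d[-drop_idx, , drop = FALSE], terms = "x")
  expect_equal(m_w$beta, m_d$beta, tolerance = 1e-9)
  expect_equal(m_w$phi, m_d$phi, tolerance = 1e-6)
})

test_that("degenerate and erroneous fits are reported", {
  expect_warning(fit_quasipoisson(c(1, 0), c(100, 0)), "zero person-time")
  d <- data.frame(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8)) # aliased
  expect_error(fit_quasipoisson(c(0, 1, 0, 2), rep(100, 4), data = d,
                                terms = c("a", "b")), "aliased")
  expect_error(fit_quasipoisson(c(1, 1), c(10, 10), weights = c(2, 1)),
               "weights")
})

test_that("Dawid-Sebastiani score matches its closed form", {
  expect_equal(dss(3, 3, 1), 0)
  expect_equal(dss(0, 1, 1), 1)
  expect_equal(dss(4, 2, 2), 2 + log(2))
  expect_equal(round(dss(4, 2, 2), 4), 2.6931)
  expect_error(dss(1, 1, 0), "variance")
})

test_that("variant screening picks the data-consistent lag and breaks ties", {
  # single variant passes through
  set.seed(31)
  y <- rpois(100, 1)
  pt <- rep(1000, 100)
  single <- screen_variants(list(v1 = list(values = rnorm(100), lag = 0,
                                           coding = "continuous")), y, pt)
  expect_equal(single$variant, "v1")
  # identical data across variants: smallest lag wins, continuous first
  x <- rnorm(100)
  tied <- screen_variants(list(
    a2 = list(values = x, lag = 2, coding = "continuous"),
    a0cat = list(values = x, lag = 0, coding = "categorical"),
    a0 = list(values = x, lag = 0, coding = "continuous")), y, pt)
  expect_equal(tied$variant, "a0")
})

test_that("screening recovers a known generative lag most of the time", {
  set.seed(55)
  hits <- 0
  reps <- 30
  for (r in 1:reps) {
    months <- 40
    x <- as.numeric(arima.sim(list(ar = 0.6), months))
    strata <- 5:months
    pt <- rep(5e4, length(strata))
    truth_lag <- 2
    y <- rpois(length(strata), exp(-6.5 + 0.6 * x[strata - truth_lag]) * pt)
    variants <- lapply(0:4, function(l) {
      list(values = x[strata - l], lag = l, coding = "continuous")
    })
    names(variants) <- paste0("lag", 0:4)
    got <- screen_variants(variants, y, pt)
    hits <- hits + (got$variant == "lag2")
  }
  expect_gte(hits / reps, 0.8)
})

test_that("model enumeration covers all subsets and is deterministic", {
  set.seed(61)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  lga <- sample(sprintf("lga%02d", 1:10), n, replace = TRUE)
  pt <- runif(n, 500, 1500)
  y <- rpois(n, exp(-5.5 + 0.7 * d$x1 - 0.5 * d$x2) * pt)
  tab <- enumerate_and_score(c("x1", "x2", "x3"), d, y, pt, lga)
  expect_equal(nrow(tab), 8) # 2^3 - 1 candidates plus the null
  expect_identical(tab,
                   enumerate_and_score(c("x1", "x2", "x3"), d, y, pt, lga))
  # the generative model ranks above the null
  gen_rank <- which(tab$terms == "x1,x2")
  null_rank <- which(tab$terms == "")
  expect_lt(gen_rank, null_rank)
  expect_error(enumerate_and_score(letters[1:9], d, y, pt, lga, cap = 8), "cap")
})

test_that("LGA-grouped cross-validation partitions cleanly and is seeded", {
  lgas <- sprintf("lga%02d", 1:20)
  f1 <- mortsae:::lga_folds(lgas, 10, seed = 4)
  expect_equal(sort(unname(unlist(f1))), lgas) # each LGA in exactly one fold
  expect_identical(f1, mortsae:::lga_folds(lgas, 10, seed = 4))
  expect_false(identical(f1, mortsae:::lga_folds(lgas, 10, seed = 5)))

  set.seed(71)
  n <- 2000
  d <- data.frame(x = rnorm(n))
  lga <- sample(lgas, n, replace = TRUE)
  pt <- runif(n, 500, 1500)
  y <- rpois(n, exp(-5 + 0.8 * d$x) * pt)
  cv_gen <- cross_validate("x", d, y, pt, lga, k = 10, seed = 2)
  cv_null <- cross_validate(character(0), d, y, pt, lga, k = 10, seed = 2)
  expect_lt(cv_gen$dss_cv, cv_null$dss_cv)
  cv_rep <- cross_validate("x", d, y, pt, lga, k = 10, seed = 2)
  expect_equal(cv_gen$dss_cv, cv_rep$dss_cv)
  expect_equal(cv_gen$scores, cv_rep$scores)
})

test_that("cross-validation never fits on test-fold outcomes", {
  set.seed(81)
  lgas <- sprintf("lga%02d", 1:10)
  n <- 1500
  d <- data.frame(x = rnorm(n))
  lga <- sample(lgas, n, replace = TRUE)
  pt <- runif(n, 500, 1500)
  y <- rpois(n, exp(-5 + 0.5 * d$x) * pt)
  cv1 <- cross_validate("x", d, y, pt, lga, k = 5, seed = 3)
  # perturb outcomes of one LGA only
  target <- lgas[1]
  y2 <- y
  y2[lga == target] <- y2[lga == target] + 5
  cv2 <- cross_validate("x", d, y2, pt, lga, k = 5, seed = 3)
  folds <- mortsae:::lga_folds(lgas, 5, seed = 3)
  fold_of <- which(vapply(folds, function(f) target %in% f, logical(1)))
  same_fold_others <- setdiff(folds[[fold_of]], target)
  # the perturbed LGA's own score changes...
  expect_false(isTRUE(all.equal(
    cv1$scores$dss[cv1$scores$lga_id == target],
    cv2$scores$dss[cv2$scores$lga_id == target])))
  # ...but predictions for other LGAs in the same fold are untouched,
  # because the training fit never saw the test fold
  for (g in same_fold_others) {
    expect_equal(cv1$scores$predicted[cv1$scores$lga_id == g],
                 cv2$scores$predicted[cv2$scores$lga_id == g])
  }
})

test_that("rate-ratio tables reproduce the Wald closed form", {
  m <- structure(list(beta = c(maize_high = 0.8286),
                      cov_beta = matrix(0.1430^2, 1, 1,
                                        dimnames = list("maize_high", "maize_high"))),
                 class = "rate_model")
  rr <- rate_ratios(m)
  expect_equal(round(rr$rr, 2), 2.29)
  expect_equal(round(rr$ci_low, 2), 1.73)
  expect_equal(round(rr$ci_high, 2), 3.03)
  # beta = 0 gives RR 1 with CI containing 1
  m0 <- structure(list(beta = c(x = 0), cov_beta = matrix(0.04, 1, 1)),
                  class = "rate_model")
  rr0 <- rate_ratios(m0)
  expect_equal(rr0$rr, 1)
  expect_lt(rr0$ci_low, 1)
  expect_gt(rr0$ci_high, 1)
  # CI width monotone in the standard error
  m_wide <- structure(list(beta = c(x = 0.5), cov_beta = matrix(0.09, 1, 1)),
                      class = "rate_model")
  m_narrow <- structure(list(beta = c(x = 0.5), cov_beta = matrix(0.01, 1, 1)),
                        class = "rate_model")
  expect_gt(rate_ratios(m_wide)$ci_high - rate_ratios(m_wide)$ci_low,
            rate_ratios(m_narrow)$ci_high - rate_ratios(m_narrow)$ci_low)
})

test_that("performance metrics follow their definitions", {
  p <- c(10, 20, 30)
  expect_equal(performance_metrics(p, p)$relative_bias, 0)
  expect_equal(performance_metrics(p, p)$mse, 0)
  expect_equal(performance_metrics(0.9 * p, p)$relative_bias, -10)
  pm <- performance_metrics(p, p, point = c(10, 20, 30),
                            ci_low = c(4, 8, 12), ci_high = c(16, 32, 48))
  expect_equal(pm$relative_precision, 60)
  expect_error(performance_metrics(p, c(0, 0, 0)), "undefined")
})

test_that("random-intercept fit degenerates to the fixed fit at sigma = 0", {
  set.seed(91)
  n <- 3000
  lga <- sample(sprintf("lga%02d", 1:12), n, replace = TRUE)
  d <- data.frame(x = rnorm(n))
  pt <- runif(n, 500, 1500)
  y <- rpois(n, exp(-5 + 0.4 * d$x) * pt) # no LGA heterogeneity
  expect_message(
    m_re <- fit_random_intercept(y, pt, lga, data = d, terms = "x"),
    "equivalent to the fixed")
  m_fx <- fit_quasipoisson(y, pt, data = d, terms = "x")
  expect_lt(m_re$sigma_u_sq, 1e-4)
  expect_equal(unname(m_re$beta), unname(m_fx$beta), tolerance = 1e-3)
})

test_that("random-intercept variance is recovered from heterogeneous LGAs", {
  set.seed(95)
  n_lga <- 50
  sigma2 <- 0.09
  u <- rnorm(n_lga, 0, sqrt(sigma2))
  rows_per <- 150
  lga <- rep(sprintf("lga%02d", 1:n_lga), each = rows_per)
  pt <- rep(1200, n_lga * rows_per)
  y <- rpois(length(lga), exp(-5 + u[as.integer(factor(lga))]) * pt)
  m <- fit_random_intercept(y, pt, lga)
  expect_gt(m$sigma_u_sq, 0.04)
  expect_lt(m$sigma_u_sq, 0.17)
  expect_equal(length(m$u_hat), n_lga)
  # predicted intercepts track the true ones
  expect_gt(cor(m$u_hat[sprintf("lga%02d", 1:n_lga)], u), 0.7)
})

test_that("prediction propagates the fixed-effect covariance", {
  set.seed(101)
  d <- data.frame(x = rbinom(200, 1, 0.5))
  pt <- runif(200, 500, 1500)
  y <- rpois(200, exp(-5 + 0.5 * d$x) * pt)
  m <- fit_quasipoisson(y, pt, data = d, terms = "x")
  pr <- predict_log_rate(m, data.frame(x = c(0, 1)))
  expect_equal(pr$m[1], unname(m$beta[1]))
  expect_equal(pr$m[2], unname(sum(m$beta)))
  # quadratic-form expansion for the binary covariate at x = 1
  s2 <- m$cov_beta[1, 1] + m$cov_beta[2, 2] + 2 * m$cov_beta[1, 2]
  expect_equal(pr$s[2]^2, s2, tolerance = 1e-12)
  expect_error(predict_log_rate(m, data.frame(z = 1)), "missing covariates")
  # training-data predictions reproduce fitted expected counts
  mu_hat <- exp(predict_log_rate(m, d)$m) * pt
  expect_equal(sum(mu_hat), sum(y), tolerance = 1e-6) # score equation
})
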