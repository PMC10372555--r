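test_that("generator is bit-identical for a fixed seed", {
  cfg <- sim_config(seed = 5, n_lgas = 6, n_months = 12, n_surveys = 8,
                    clusters_per_survey = 4, households_per_cluster = 6)
  a <- simulate_crisis(cfg)
  b <- simulate_crisis(cfg)
  expect_identical(a$surface, b$surface)
  expect_identical(a$households, b$households)
  expect_identical(a$surveys, b$surveys)
  expect_identical(a$sources, b$sources)
  expect_identical(a$flows, b$flows)
  expect_identical(a$predictors, b$predictors)
})

test_that("constant-surface limit: beta = 0, sigma_u = 0 gives flat rates", {
  cfg <- sim_config(seed = 3, n_lgas = 5, n_months = 8,
                    beta = c(x1 = 0, x2 = 0), sigma_u_sq = 0,
                    cdr0 = 0.5, u5dr0 = 1.0)
  surf <- generate_truth(cfg)
  expect_equal(surf$rates$true_cdr, rep(0.5, nrow(surf$rates)))
  expect_equal(surf$rates$true_u5dr, rep(1.0, nrow(surf$rates)))
})

test_that("random-intercept draws have the configured variance", {
  # pool u across repeated seeds; scaled sample variance is chi-square
  sigma2 <- 0.09
  n_lga <- 50
  reps <- 20
  u <- unlist(lapply(1:reps, function(s) {
    generate_truth(sim_config(seed = s, n_lgas = n_lga, n_months = 2,
                              sigma_u_sq = sigma2))$u
  }))
  n <- length(u)
  stat <- (n - 1) * var(u) / sigma2
  expect_gt(stat, qchisq(0.0005, n - 1))
  expect_lt(stat, qchisq(0.9995, n - 1))
})

test_that("a zero-rate surface yields zero deaths everywhere", {
  cfg <- sim_config(seed = 9, n_lgas = 4, n_months = 6, n_surveys = 8,
                    clusters_per_survey = 4, households_per_cluster = 8)
  surf <- generate_truth(cfg)
  surf$rates$true_cdr[] <- 0
  surf$rates$true_u5dr[] <- 0
  svy <- simulate_surveys(surf, cfg)
  expect_true(all(svy$households$deaths_all == 0))
  expect_true(all(svy$households$deaths_under5 == 0))
})

test_that("pooled survey CDR matches the person-time-weighted true rate", {
  cfg <- sim_config(seed = 21, n_lgas = 10, n_months = 24, n_surveys = 60,
                    clusters_per_survey = 25, households_per_cluster = 20,
                    sigma_u_sq = 0.05)
  sim <- simulate_crisis(cfg)
  hh <- sim$households
  meta <- sim$surveys[match(hh$survey_id, sim$surveys$survey_id), ]
  pt <- person_time(hh, meta$recall_days)
  expect_gt(sum(pt$person_days) / 365, 5e4) # enough person-years for the bound
  pooled <- 1e4 * sum(hh$deaths_all) / sum(pt$person_days)

  # oracle: expected pooled rate from the true surface, person-time weighted
  # via each survey's day-weighted window mean log rate
  log_rate <- log(sim$surface$rates$true_cdr)
  key <- paste(sim$surface$rates$lga_id, sim$surface$rates$month)
  months <- sim$surface$months
  svy_rate <- vapply(seq_len(nrow(sim$surveys)), function(i) {
    s <- sim$surveys[i, ]
    w <- vapply(months, function(m) {
      max(0, as.integer(min(month_end(m), s$recall_end) -
                          max(month_start(m), s$recall_start)) + 1)
    }, numeric(1))
    idx <- match(paste(s$lga_id, months), key)
    exp(sum(w / sum(w) * log_rate[idx]))
  }, numeric(1))
  pd_by_svy <- tapply(pt$person_days, hh$survey_id, sum)[sim$surveys$survey_id]
  truth <- sum(svy_rate * pd_by_svy) / sum(pd_by_svy)

  # binomial-type Monte-Carlo bound on the pooled death count
  se <- 1e4 * sqrt(sum(hh$deaths_all)) / sum(pt$person_days)
  expect_lt(abs(pooled - truth), 4 * se)
})

test_that("household expected deaths follow rate x person-time / 10,000", {
  # 5 members over 100 days at CDR 1.0 -> 0.05 expected deaths; check via the
  # empirical mean over many pure-Poisson households on a flat surface
  cfg <- sim_config(seed = 13, n_lgas = 2, n_states = 1, n_months = 12, n_surveys = 40,
                    clusters_per_survey = 25, households_per_cluster = 40,
                    beta = c(x1 = 0), sigma_u_sq = 0, cdr0 = 1.0, u5dr0 = 1.0,
                    birth_rate = 0, arrival_rate = 0, departure_rate = 0)
  expect_equal(1.0 * 5 * 100 / 1e4, 0.05) # the unit identity itself
  sim <- simulate_crisis(cfg)
  hh <- sim$households
  meta <- sim$surveys[match(hh$survey_id, sim$surveys$survey_id), ]
  expected <- 1.0 * (hh$n_current_members * meta$recall_days) / 1e4
  ratio <- sum(hh$deaths_all) / sum(expected)
  expect_lt(abs(ratio - 1), 4 / sqrt(sum(expected)))
})

test_that("person-time bookkeeping matches half-day enumeration", {
  sim <- small_sim(seed = 31)
  hh <- sim$households
  meta <- sim$surveys[match(hh$survey_id, sim$surveys$survey_id), ]
  pt <- person_time(hh, meta$recall_days)
  idx <- seq(1, nrow(hh), by = 37)
  for (i in idx) {
    oracle <- person_time_enum(hh[i, ], meta$recall_days[i])
    expect_equal(pt$person_days[i], unname(oracle["person_days"]))
    expect_equal(pt$child_days[i], unname(oracle["child_days"]))
  }
})

test_that("displacement flows conserve people and respect the zero config", {
  cfg0 <- sim_config(seed = 7, n_lgas = 6, n_months = 10, displacement_rate = 0)
  pop0 <- simulate_population(cfg0)
  expect_equal(nrow(pop0$flows), 0)

  cfg <- sim_config(seed = 7, n_lgas = 6, n_months = 10)
  pop <- simulate_population(cfg)
  expect_gt(nrow(pop$flows), 0)
  # every departure is an arrival somewhere (internal rows) or external
  internal <- pop$flows[pop$flows$to_lga != "external", ]
  out_by <- tapply(internal$persons, internal$from_lga, sum)
  in_by <- tapply(internal$persons, internal$to_lga, sum)
  expect_equal(sum(out_by), sum(in_by))
  # at least two sources per LGA with distinct reference dates
  for (g in unique(pop$sources$lga_id)) {
    s <- pop$sources[pop$sources$lga_id == g, ]
    expect_gte(nrow(s), 2)
    expect_equal(anyDuplicated(s$reference_date), 0)
  }
})

test_that("invalid configuration names the offending field", {
  expect_error(sim_config(recall_range = c(10, 500)), "recall_range")
  expect_error(sim_config(n_lgas = 0), "n_lgas")
  expect_error(sim_config(missing_frac = 1.5), "missing_frac")
  expect_error(sim_config(beta = c(0.1, 0.2)), "beta") # unnamed
})

test_that("frailty switch produces overdispersed counts", {
  cfg <- sim_config(seed = 17, n_lgas = 6, n_months = 12, n_surveys = 30,
                    clusters_per_survey = 20, households_per_cluster = 20,
                    beta = c(x1 = 0), sigma_u_sq = 0, frailty_var = 6,
                    cdr0 = 2, u5dr0 = 4, recall_range = c(150, 250))
  sim <- simulate_crisis(cfg)
  hh <- sim$households
  meta <- sim$surveys[match(hh$survey_id, sim$surveys$survey_id), ]
  pt <- person_time(hh, meta$recall_days)
  fit <- fit_quasipoisson(hh$deaths_all, pt$person_days)
  expect_gt(fit$phi, 1.5)
})
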