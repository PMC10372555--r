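# Independent oracles used across tests: brute-force enumeration and a
# hand-coded IRLS fitter, deliberately separate from the package's code paths.

# Half-day enumeration of household person-time: continuously present members
# are counted at every half-day step, event persons (deaths, departures before
# the midpoint; births, arrivals after it) at the steps on their side of the
# recall midpoint.
person_time_enum <- function(rec, R) {
  steps <- seq(0.25, R, by = 0.5) # midpoints of half-day intervals
  total <- 0
  child <- 0
  for (t in steps) {
    leavers <- if (t <= R / 2) rec$deaths_all + rec$departures else 0
    joiners <- if (t > R / 2) rec$births + rec$arrivals else 0
    total <- total + rec$n_current_members + leavers + joiners
    child <- child + rec$n_current_under5 + if (t <= R / 2) rec$deaths_under5 else 0
  }
  c(person_days = total * 0.5, child_days = child * 0.5)
}

# Daily enumeration of a recall-window mean: every calendar day carries its
# month's value.
recall_mean_enum <- function(values, months, start, end) {
  days <- seq(as.Date(start), as.Date(end), by = "day")
  mean(values[match(format(days, "%Y-%m"), months)])
}

# Independently coded IRLS for a Poisson log-link model with offset and prior
# weights (the quasi-Poisson point estimates).
irls_poisson <- function(X, y, offset, w = rep(1, length(y)), tol = 1e-12) {
  beta <- numeric(ncol(X))
  beta[1] <- log(sum(w * y) / sum(w * exp(offset)))
  for (it in 1:200) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    W <- w * mu
    z <- eta - offset + (y - mu) / mu
    beta_new <- drop(solve(crossprod(X, W * X), crossprod(X, W * z)))
    done <- max(abs(beta_new - beta)) < tol
    beta <- beta_new
    if (done) break
  }
  beta
}

# Sort-and-interpolate percentile (type-7), coded independently of quantile()
percentile_interp <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small ready-made synthetic run shared by several test files
small_sim <- function(seed = 11, ...) {
  simulate_crisis(sim_config(seed = seed, n_lgas = 10, n_months = 18,
                             n_surveys = 20, clusters_per_survey = 8,
                             households_per_cluster = 10, ...))
}
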