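# Household-level mortality rate models: weighted quasi-Poisson offset
# regression, optional LGA random intercept, Dawid-Sebastiani scoring,
# predictor screening, model enumeration and LGA-grouped cross-validation.

build_design <- function(term_labels, data, xlevels = NULL) {
  if (!length(term_labels)) {
    return(matrix(1, nrow = if (is.null(data)) 1L else nrow(data),
                  dimnames = list(NULL, "(Intercept)")))
  }
  tt <- stats::terms(stats::reformulate(term_labels))
  stats::model.matrix(tt, data = data, xlev = xlevels)
}

term_xlevels <- function(data, term_labels) {
  vars <- unique(unlist(strsplit(term_labels, ":", fixed = TRUE)))
  vars <- intersect(vars, names(data))
  lv <- lapply(data[vars], function(x) if (is.factor(x)) levels(x) else NULL)
  lv[!vapply(lv, is.null, logical(1))]
}

#' Fit a weighted quasi-Poisson death-rate model
#'
#' Log-link count regression of household deaths with person-time as an
#' offset: `deaths ~ terms + offset(log(person_days))`, weighted by survey
#' robustness weights. The dispersion `phi` is the Pearson chi-square divided
#' by the residual degrees of freedom; the coefficient covariance is scaled by
#' `max(phi, 1)` (variance shrinkage below Poisson is not credible for
#' mortality counts; the raw `phi` is reported unaltered).
#'
#' @param deaths non-negative household death counts.
#' @param person_days positive household person-time; rows with zero
#'   person-time are dropped with a warning.
#' @param data data frame of covariates (factors allowed); `NULL` fits an
#'   intercept-only model.
#' @param terms character vector of model term labels referring to columns of
#'   `data` (interactions as `"a:b"`); empty fits the null model.
#' @param weights robustness weights in `[0, 1]`; default 1.
#' @return an object of class `rate_model`: coefficients `beta`, phi-scaled
#'   covariance `cov_beta`, dispersion `phi`, `sigma_u_sq`/`u_hat` (absent
#'   here), the term labels and factor levels needed for prediction, and the
#'   training deviance/df.
#' @examples
#' m <- fit_quasipoisson(c(1, 0, 3), c(100, 200, 100))
#' m$beta      # log(4/400) = -4.6052
#' m$phi       # 3
#' @export
fit_quasipoisson <- function(deaths, person_days, data = NULL,
                             terms = character(0), weights = NULL) {
  n <- length(deaths)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(person_days) == n, length(weights) == n)
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  keep <- person_days > 0
  if (!all(keep)) {
    warning(sum(!keep), " rows with zero person-time dropped", call. = FALSE)
    deaths <- deaths[keep]; person_days <- person_days[keep]
    weights <- weights[keep]
    if (!is.null(data)) data <- data[keep, , drop = FALSE]
  }
  df <- if (is.null(data)) data.frame(row.names = seq_along(deaths)) else as.data.frame(data)
  df$.deaths <- deaths
  df$.off <- log(person_days)
  df$.w <- weights
  rhs <- if (length(terms)) paste(c(terms, "offset(.off)"), collapse = " + ") else "offset(.off)"
  fml <- stats::as.formula(paste(".deaths ~", rhs))
  fit <- stats::glm(fml, family = stats::quasipoisson(), data = df, weights = .w)
  if (!fit$converged) stop("quasi-Poisson fit did not converge after ",
                           fit$iter, " IRLS iterations", call. = FALSE)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("collinear design: aliased terms ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  phi <- sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
  phi_scale <- max(phi, 1)
  cov_unscaled <- summary(fit, dispersion = 1)$cov.unscaled
  structure(list(beta = beta,
                 cov_beta = cov_unscaled * phi_scale,
                 phi = phi, phi_scale = phi_scale,
                 sigma_u_sq = NULL, u_hat = NULL,
                 term_labels = terms,
                 xlevels = if (is.null(data)) list() else term_xlevels(df, terms),
                 weights_used = weights, n_households = length(deaths),
                 deviance = stats::deviance(fit),
                 df_residual = stats::df.residual(fit),
                 engine = "glm"),
            class = "rate_model")
}

#' Fit the mixed model with an LGA random intercept
#'
#' Adds a centred-normal random intercept per LGA to the quasi-Poisson fit,
#' estimated by Laplace-approximated maximum likelihood (via glmmTMB's
#' Poisson family); overdispersion is then handled as in the fixed fit, by
#' scaling the fixed-effect covariance with the Pearson dispersion. If the
#' variance estimate collapses to zero the fit is flagged as equivalent to
#' the fixed-effects model.
#'
#' @inheritParams fit_quasipoisson
#' @param lga LGA identifier per household (grouping factor).
#' @return a `rate_model` with `sigma_u_sq` and named `u_hat` filled in.
#' @export
fit_random_intercept <- function(deaths, person_days, lga, data = NULL,
                                 terms = character(0), weights = NULL) {
  n <- length(deaths)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(unique(lga[deaths > 0])) < 5) {
    stop("need at least 5 LGAs with events for a random intercept", call. = FALSE)
  }
  keep <- person_days > 0
  if (!all(keep)) {
    warning(sum(!keep), " rows with zero person-time dropped", call. = FALSE)
    deaths <- deaths[keep]; person_days <- person_days[keep]
    weights <- weights[keep]; lga <- lga[keep]
    if (!is.null(data)) data <- data[keep, , drop = FALSE]
  }
  df <- if (is.null(data)) data.frame(row.names = seq_along(deaths)) else as.data.frame(data)
  df$.deaths <- deaths
  df$.off <- log(person_days)
  df$.w <- weights
  df$.lga <- factor(lga)
  rhs <- paste(c(terms, "offset(.off)", "(1 | .lga)"), collapse = " + ")
  fml <- stats::as.formula(paste(".deaths ~", rhs))
  fit <- glmmTMB::glmmTMB(fml, family = stats::poisson(), data = df, weights = .w)
  beta <- glmmTMB::fixef(fit)$cond
  p <- length(beta)
  pearson <- stats::residuals(fit, type = "pearson")
  phi <- sum(pearson^2) / (length(deaths) - p)
  phi_scale <- max(phi, 1)
  vc <- glmmTMB::VarCorr(fit)$cond$.lga
  sigma_u_sq <- as.numeric(vc[1, 1])
  re <- glmmTMB::ranef(fit)$cond$.lga
  u_hat <- stats::setNames(re[[1]], rownames(re))
  if (sigma_u_sq < 1e-8) {
    message("random-intercept variance estimated at zero; ",
            "fit is equivalent to the fixed-effects model")
  }
  structure(list(beta = beta,
                 cov_beta = as.matrix(stats::vcov(fit)$cond) * phi_scale,
                 phi = phi, phi_scale = phi_scale,
                 sigma_u_sq = sigma_u_sq, u_hat = u_hat,
                 term_labels = terms,
                 xlevels = if (is.null(data)) list() else term_xlevels(df, terms),
                 weights_used = weights, n_households = length(deaths),
                 deviance = -2 * as.numeric(stats::logLik(fit)),
                 df_residual = length(deaths) - p,
                 engine = "glmmTMB"),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> %d households, %d terms, phi = %.3f%s\n",
              x$n_households, length(x$term_labels), x$phi,
              if (!is.null(x$sigma_u_sq)) sprintf(", sigma_u^2 = %.4f", x$sigma_u_sq) else ""))
  print(rate_ratios(x))
  invisible(x)
}

#' Predict the linear predictor and its standard error
#'
#' Returns `m = x'beta (+ u_hat[lga])` and `s = sqrt(x' cov_beta x)` per row
#' of `newdata`. The standard error uses the fixed-effect covariance only:
#' toll intervals propagate model (coefficient) error and no other source.
#'
#' @param model a `rate_model`.
#' @param newdata covariate data frame (one row per stratum).
#' @param lga optional LGA ids matched against `u_hat`; unknown LGAs get
#'   `u = 0` (population-level prediction).
#' @param include_u include the predicted random intercept where available.
#' @return data frame with columns `m` (log rate per person-day) and `s`.
#' @export
predict_log_rate <- function(model, newdata = NULL, lga = NULL, include_u = TRUE) {
  miss <- setdiff(unique(unlist(strsplit(model$term_labels, ":", fixed = TRUE))),
                  names(newdata))
  if (length(miss)) {
    stop("missing covariates for prediction: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  X <- build_design(model$term_labels, newdata, model$xlevels)
  m <- drop(X %*% model$beta)
  s <- sqrt(rowSums((X %*% model$cov_beta) * X))
  if (include_u && !is.null(model$u_hat) && !is.null(lga)) {
    u <- model$u_hat[as.character(lga)]
    u[is.na(u)] <- 0
    m <- m + u
  }
  data.frame(m = m, s = s)
}

#' Dawid-Sebastiani score
#'
#' Proper scoring rule for a predictive mean and variance:
#' `(observed - mean)^2 / variance + log(variance)`. Lower is better.
#'
#' @param observed,predicted_mean,predicted_variance numeric vectors;
#'   variances must be positive.
#' @return numeric vector of scores.
#' @examples
#' dss(4, 2, 2) # 2 + log(2)
#' @export
dss <- function(observed, predicted_mean, predicted_variance) {
  if (any(predicted_variance <= 0)) stop("predictive variance must be positive", call. = FALSE)
  (observed - predicted_mean)^2 / predicted_variance + log(predicted_variance)
}

# Sum household predictions and observations to LGA level and score them.
# Predictive variance at LGA level is phi * predicted mean (quasi-Poisson).
lga_scores <- function(model, data, deaths, person_days, lga, include_u = TRUE) {
  pr <- predict_log_rate(model, data, lga = lga, include_u = include_u)
  mu <- exp(pr$m) * person_days
  pred <- tapply(mu, lga, sum)
  obs <- tapply(deaths, lga, sum)
  v <- pmax(model$phi_scale * pred, .Machine$double.eps)
  data.frame(lga_id = names(pred), observed = as.numeric(obs),
             predicted = as.numeric(pred),
             dss = dss(as.numeric(obs), as.numeric(pred), as.numeric(v)),
             sq_error = (as.numeric(obs) - as.numeric(pred))^2)
}

#' Screen lag/coding variants of one predictor
#'
#' Fits one univariate weighted quasi-Poisson model per variant and keeps the
#' variant most consistent with the data: lowest p-value on a
#' dispersion-scaled F test against the null (offset-only) model. Ties are
#' broken by the smaller lag, then continuous before categorical coding.
#'
#' @param variants named list; each element has `values` (covariate vector,
#'   numeric or factor), `lag` (months) and `coding` (`"continuous"` or
#'   `"categorical"`).
#' @param deaths,person_days,weights household outcome, exposure and weights.
#' @return a list: `variant` (the winning name), `p_value`, and `table` of all
#'   variants' tests. Variants whose fit fails are dropped with a warning.
#' @export
screen_variants <- function(variants, deaths, person_days, weights = NULL) {
  stopifnot(length(variants) >= 1, !is.null(names(variants)))
  null_fit <- fit_quasipoisson(deaths, person_days, weights = weights)
  rows <- list()
  for (nm in names(variants)) {
    v <- variants[[nm]]
    fit <- tryCatch(
      fit_quasipoisson(deaths, person_days,
                       data = stats::setNames(data.frame(v$values), "x"),
                       terms = "x", weights = weights),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("variant ", nm, " failed to fit and was dropped", call. = FALSE)
      next
    }
    df1 <- null_fit$df_residual - fit$df_residual
    fstat <- ((null_fit$deviance - fit$deviance) / df1) / max(fit$phi, 1e-12)
    p <- stats::pf(fstat, df1, fit$df_residual, lower.tail = FALSE)
    rows[[nm]] <- data.frame(variant = nm, lag = v$lag, coding = v$coding,
                             f = fstat, p_value = p)
  }
  if (!length(rows)) {
    warning("all variants failed; variable dropped", call. = FALSE)
    return(NULL)
  }
  tab <- do.call(rbind, rows)
  ord <- order(round(tab$p_value, 12), tab$lag,
               match(tab$coding, c("continuous", "categorical")))
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(variant = tab$variant[1], p_value = tab$p_value[1], table = tab)
}

#' Enumerate candidate multivariable models
#'
#' Fits every non-empty subset of the shortlisted predictor columns and ranks
#' the candidates (plus the null model) by mean in-sample LGA-level
#' Dawid-Sebastiani score; ties favour fewer terms, then lexicographic term
#' order. The top-ranked candidates go on to cross-validation.
#'
#' @param shortlist character vector of covariate column names in `data`.
#' @param data covariate data frame.
#' @param deaths,person_days,lga,weights household vectors.
#' @param cap maximum shortlist size (default 8; `2^8 - 1` fits).
#' @return data frame ranked best-first: `terms` (comma-joined), `n_terms`,
#'   `dss_insample`, `phi`.
#' @export
enumerate_and_score <- function(shortlist, data, deaths, person_days, lga,
                                weights = NULL, cap = 8) {
  if (length(shortlist) > cap) {
    stop(sprintf("shortlist of %d exceeds the cap of %d", length(shortlist), cap),
         call. = FALSE)
  }
  shortlist <- sort(shortlist)
  subsets <- c(list(character(0)),
               unlist(lapply(seq_along(shortlist), function(k) {
                 utils::combn(shortlist, k, simplify = FALSE)
               }), recursive = FALSE))
  rows <- lapply(subsets, function(tm) {
    fit <- fit_quasipoisson(deaths, person_days, data = data, terms = tm,
                            weights = weights)
    sc <- lga_scores(fit, data, deaths, person_days, lga)
    data.frame(terms = paste(tm, collapse = ","), n_terms = length(tm),
               dss_insample = mean(sc$dss), phi = fit$phi)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$dss_insample, tab$n_terms, tab$terms), ]
  rownames(tab) <- NULL
  tab
}

# seeded partition of LGAs into k folds of near-equal size
lga_folds <- function(lgas, k, seed) {
  lgas <- sort(unique(as.character(lgas)))
  if (length(lgas) < k) stop("need at least k LGAs for k-fold CV", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(lgas)))
  split(lgas, fold)
}

#' LGA-grouped k-fold cross-validation
#'
#' Partitions LGAs into `k` folds (seeded). Per fold the model is refitted on
#' the training LGAs only and used to predict held-out households
#' (population-level, i.e. without the held-out LGAs' random intercepts);
#' predictions and observations are summed to LGA level and scored with the
#' Dawid-Sebastiani rule (predictive variance `phi * mean`) and squared
#' error. Folds whose test LGAs hold zero deaths are skipped with a warning.
#'
#' @param terms model term labels.
#' @param data,deaths,person_days,lga,weights household-level inputs.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param random_intercept refit with the LGA random intercept per fold.
#' @return a `performance_report` list: `dss_cv`/`dss_cv_sd`,
#'   `mse_cv`/`mse_cv_sd`, `relative_bias` (percent), `n_lgas`, `k`, and the
#'   per-LGA score table `scores`.
#' @export
cross_validate <- function(terms, data, deaths, person_days, lga,
                           weights = NULL, k = 10, seed = 1,
                           random_intercept = FALSE) {
  folds <- lga_folds(lga, k, seed)
  if (is.null(weights)) weights <- rep(1, length(deaths))
  score_list <- list()
  for (f in seq_along(folds)) {
    test <- lga %in% folds[[f]]
    if (!any(test)) next
    if (sum(deaths[test]) == 0) {
      warning("fold ", f, " has zero deaths in its test LGAs; skipped", call. = FALSE)
      next
    }
    fit <- if (random_intercept) {
      fit_random_intercept(deaths[!test], person_days[!test], lga[!test],
                           data = data[!test, , drop = FALSE], terms = terms,
                           weights = weights[!test])
    } else {
      fit_quasipoisson(deaths[!test], person_days[!test],
                       data = data[!test, , drop = FALSE], terms = terms,
                       weights = weights[!test])
    }
    score_list[[f]] <- lga_scores(fit, data[test, , drop = FALSE], deaths[test],
                                  person_days[test], lga[test], include_u = FALSE)
  }
  scores <- do.call(rbind, score_list)
  structure(list(dss_cv = mean(scores$dss), dss_cv_sd = stats::sd(scores$dss),
                 mse_cv = mean(scores$sq_error), mse_cv_sd = stats::sd(scores$sq_error),
                 relative_bias = 100 * (sum(scores$predicted) - sum(scores$observed)) /
                   sum(scores$observed),
                 n_lgas = nrow(scores), k = k, scores = scores),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> CV-DSS %.1f (%.1f), CV-MSE %.1f (%.1f), relative bias %+.1f%% over %d LGAs\n",
              x$dss_cv, x$dss_cv_sd, x$mse_cv, x$mse_cv_sd, x$relative_bias, x$n_lgas))
  invisible(x)
}

#' Predictive performance metrics
#'
#' Relative bias is the percentage difference between summed predictions and
#' summed observations; relative precision is the mean ratio of the 95% CI
#' half-width to the point estimate, in +/- percent; MSE is the mean squared
#' stratum-level error.
#'
#' @param predicted,observed aligned stratum-level vectors.
#' @param point,ci_low,ci_high optional stratum estimates with interval
#'   bounds, for relative precision.
#' @return list with `relative_bias`, `mse`, and (when intervals are given)
#'   `relative_precision`.
#' @export
performance_metrics <- function(predicted, observed, point = NULL,
                                ci_low = NULL, ci_high = NULL) {
  if (sum(observed) == 0) stop("total observed is zero: relative bias undefined", call. = FALSE)
  out <- list(relative_bias = 100 * (sum(predicted) - sum(observed)) / sum(observed),
              mse = mean((predicted - observed)^2))
  if (!is.null(point)) {
    out$relative_precision <- 100 * mean((ci_high - ci_low) / 2 / point)
  }
  out
}

#' Rate-ratio table for a fitted model
#'
#' Exponentiated coefficients with Wald 95% confidence intervals and p-values
#' from the phi-scaled covariance.
#'
#' @param model a `rate_model`.
#' @param level confidence level (default 0.95).
#' @return data frame: `term`, `rr`, `ci_low`, `ci_high`, `p_value`.
#' @export
rate_ratios <- function(model, level = 0.95) {
  se <- sqrt(diag(model$cov_beta))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(model$beta),
             rr = exp(model$beta),
             ci_low = exp(model$beta - z * se),
             ci_high = exp(model$beta + z * se),
             p_value = 2 * stats::pnorm(-abs(model$beta / se)),
             row.names = NULL)
}

#' Run the full predictor-selection procedure
#'
#' The five stages, in order: (i) screen each variable's lag/coding variants
#' by F-test against the null; (ii) combine the winners into all possible
#' multivariable models and rank by in-sample LGA-level DSS; (iii)
#' cross-validate the top candidates on LGA-grouped k-fold CV and pick the
#' lowest mean CV-DSS (ties: fewer terms, then lexicographic); (iv) test
#' allowed pairwise interactions among the selected main effects, keeping
#' those that improve CV-DSS; (v) refit with the LGA random intercept and
#' retain the mixed model if its CV-DSS is lower.
#'
#' @param variants_by_variable named list (one entry per variable) of variant
#'   lists as accepted by [screen_variants()].
#' @param deaths,person_days,lga,weights household-level vectors.
#' @param k,seed cross-validation folds and seed.
#' @param cap shortlist cap for enumeration (default 8).
#' @param top_k number of enumerated candidates carried to CV (default 5).
#' @param interactions allowed interaction pairs, a list of 2-vectors of
#'   variable names; `NULL` tests none.
#' @param mixed if `FALSE`, stage (v) is skipped and the fixed-effects model
#'   is returned.
#' @return list: `model` (the final `rate_model`), `terms`, `screen` (per
#'   variable), `candidates` (enumeration table), `cv` (final
#'   `performance_report`), `mixed_retained`.
#' @export
select_model <- function(variants_by_variable, deaths, person_days, lga,
                         weights = NULL, k = 10, seed = 1, cap = 8,
                         top_k = 5, interactions = NULL, mixed = TRUE) {
  screened <- list()
  covars <- list()
  for (v in names(variants_by_variable)) {
    sc <- screen_variants(variants_by_variable[[v]], deaths, person_days, weights)
    if (is.null(sc)) next
    screened[[v]] <- sc
    covars[[v]] <- variants_by_variable[[v]][[sc$variant]]$values
  }
  data <- as.data.frame(covars)
  shortlist <- names(covars)
  cand <- enumerate_and_score(shortlist, data, deaths, person_days, lga,
                              weights = weights, cap = cap)
  cand_cv <- utils::head(cand, top_k)
  cvs <- lapply(cand_cv$terms, function(tm) {
    tms <- if (nzchar(tm)) strsplit(tm, ",", fixed = TRUE)[[1]] else character(0)
    cross_validate(tms, data, deaths, person_days, lga, weights, k, seed)
  })
  cand_cv$dss_cv <- vapply(cvs, function(x) x$dss_cv, numeric(1))
  ord <- order(cand_cv$dss_cv, cand_cv$n_terms, cand_cv$terms)
  best_i <- ord[1]
  terms <- if (nzchar(cand_cv$terms[best_i])) {
    strsplit(cand_cv$terms[best_i], ",", fixed = TRUE)[[1]]
  } else character(0)
  best_cv <- cvs[[best_i]]

  if (!is.null(interactions) && length(terms) >= 2) {
    for (pair in interactions) {
      if (all(pair %in% terms)) {
        tm2 <- c(terms, paste(pair, collapse = ":"))
        cv2 <- cross_validate(tm2, data, deaths, person_days, lga, weights, k, seed)
        if (cv2$dss_cv < best_cv$dss_cv) {
          terms <- tm2
          best_cv <- cv2
        }
      }
    }
  }

  fixed_fit <- fit_quasipoisson(deaths, person_days, data = data, terms = terms,
                                weights = weights)
  mixed_retained <- FALSE
  final <- fixed_fit
  cv_mixed <- if (!mixed) NULL else tryCatch(
    cross_validate(terms, data, deaths, person_days, lga, weights, k, seed,
                   random_intercept = TRUE),
    error = function(e) NULL)
  if (!is.null(cv_mixed) && cv_mixed$dss_cv < best_cv$dss_cv) {
    final <- fit_random_intercept(deaths, person_days, lga, data = data,
                                  terms = terms, weights = weights)
    best_cv <- cv_mixed
    mixed_retained <- TRUE
  }
  list(model = final, terms = terms, data = data, screen = screened,
       candidates = cand_cv, cv = best_cv, mixed_retained = mixed_retained)
}
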