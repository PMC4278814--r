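# Interval-censored Poisson establishment model with a time-dependent
# exposure covariate.
#
# Establishment of migrants at site i in year t follows a Poisson process
# with yearly intensity lambda_i(t) = exp(beta0 + beta1 * x_i(t)), where
# x_i(t) is the cumulative trajectory-endpoint count in the site's grid
# cell.  The yearly survival probability is exp(-lambda_i(t)).  Surveys
# are annual, so first colonization is only known to lie in the interval
# (last absence year, detection year]; sites never colonized are
# right-censored at their last survey year.

site_intervals <- function(exposure, survey) {
  x <- exposure$x
  yrs <- exposure$years
  sites <- unique(survey$site_id)
  miss <- setdiff(sites, rownames(x))
  if (length(miss)) stop("exposure missing site(s): ", paste(miss, collapse = ", "))
  out <- vector("list", length(sites))
  names(out) <- sites
  for (s in sites) {
    rows <- survey[survey$site_id == s, ]
    rows <- rows[order(rows$year), ]
    if (any(!rows$year %in% yrs))
      stop("exposure does not cover all survey years for site ", s)
    xi <- x[s, match(rows$year, yrs)]
    if (any(rows$detected)) {
      b_idx <- which(rows$detected)[1]
      a_idx <- b_idx - 1L   # last recorded absence (0 when detected at first survey)
      out[[s]] <- list(x_before = xi[seq_len(a_idx)],
                       x_interval = xi[(a_idx + 1L):b_idx], event = TRUE)
    } else {
      out[[s]] <- list(x_before = xi, x_interval = numeric(0), event = FALSE)
    }
  }
  out
}

#' Log-likelihood of the interval-censored establishment model
#'
#' With `lambda_i(t) = exp(beta0 + beta1 * x_i(t))`, a site observed
#' absent over years T contributes `-sum_T lambda_i(t)`; a site first
#' detected in the interval (a, b] contributes
#' `-sum_{t<=a} lambda_i(t) + log(1 - exp(-sum_{a<t<=b} lambda_i(t)))`.
#'
#' @param beta0 log baseline intensity (per year).
#' @param beta1 effect per unit exposure count.
#' @param exposure an [exposure_series()].
#' @param survey a [survey_table()].
#' @return The log-likelihood (scalar).
#' @export
establishment_loglik <- function(beta0, beta1, exposure, survey) {
  if (!is.finite(beta0) || !is.finite(beta1))
    stop("non-finite parameters")
  if (nrow(survey) == 0) stop("empty survey")
  iv <- site_intervals(exposure, survey)
  .loglik_intervals(beta0, beta1, iv)
}

.loglik_intervals <- function(beta0, beta1, iv) {
  ll <- 0
  for (s in iv) {
    lam_before <- exp(beta0 + beta1 * s$x_before)
    ll <- ll - sum(lam_before)
    if (s$event) {
      cum <- sum(exp(beta0 + beta1 * s$x_interval))
      # log(1 - exp(-cum)) computed stably
      ll <- ll + if (cum > 1e-8) log1p(-exp(-cum)) else log(cum) + log1p(-cum / 2)
    }
  }
  ll
}

#' Fit the interval-censored Poisson establishment model
#'
#' Maximum-likelihood fit of [establishment_loglik()].  The fit uses
#' deterministic multi-start (beta1 = 0 and a moment-based guess) BFGS
#' with a Nelder-Mead polish, and a profile-likelihood 95% confidence
#' interval for `beta1` (chi-square(1) cutoff 3.84).
#'
#' @param exposure an [exposure_series()].
#' @param survey a [survey_table()].
#' @param null_model if `TRUE` fix `beta1 = 0` (intercept-only null).
#' @param ci compute the profile CI for `beta1` (skipped for the null).
#' @param conf_level confidence level of the profile interval.
#' @return An object of class `establishment_fit` with elements `beta0`,
#'   `beta1`, `loglik`, `ci_beta1`, `n_events`, `n_censored`, `scenario`.
#' @export
establishment_fit <- function(exposure, survey, null_model = FALSE,
                              ci = !null_model, conf_level = 0.95) {
  iv <- site_intervals(exposure, survey)
  n_events <- sum(vapply(iv, `[[`, TRUE, "event"))
  n_censored <- length(iv) - n_events
  if (n_events < 1) stop("establishment model needs at least one event")
  xs <- unlist(lapply(iv, function(s) c(s$x_before, s$x_interval)))
  if (!null_model && all(xs == xs[1]))
    stop("exposure covariate is constant; beta1 is not identifiable")

  nll0 <- function(b0) -.loglik_intervals(b0, 0, iv)
  o0 <- optimize(nll0, c(-30, 10), tol = 1e-12)
  # divergence to +/- infinity shows up as a flat profile at the bracket end
  b0_boundary <- o0$minimum < -29.5 || o0$minimum > 9.5 ||
    nll0(10) <= o0$objective + 1e-8 || nll0(-30) <= o0$objective + 1e-8
  if (null_model) {
    fit <- structure(list(beta0 = o0$minimum, beta1 = 0,
                          loglik = -o0$objective, ci_beta1 = c(NA_real_, NA_real_),
                          n_events = n_events, n_censored = n_censored,
                          null_model = TRUE, scenario = exposure$scenario,
                          boundary = b0_boundary),
                     class = "establishment_fit")
    if (fit$boundary) warning("beta0 estimate at boundary; model degenerate")
    return(fit)
  }

  nll <- function(p) {
    v <- -.loglik_intervals(p[1], p[2], iv)
    if (!is.finite(v)) 1e10 else v
  }
  # moment guess: scale beta1 so that beta1 * typical exposure ~ 1
  xq <- stats::quantile(xs[xs > 0], 0.9, names = FALSE)
  guess <- if (is.na(xq) || xq == 0) 0.001 else 1 / xq
  starts <- list(c(o0$minimum, 0), c(o0$minimum, guess), c(o0$minimum, -guess))
  best <- NULL
  for (st in starts) {
    o <- optim(st, nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
    o <- optim(o$par, nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  beta0 <- best$par[1]; beta1 <- best$par[2]
  loglik <- -best$value
  boundary <- beta0 > 9.5 || beta0 < -25
  if (boundary) warning("beta0 estimate at boundary; model degenerate")

  ci_b1 <- c(NA_real_, NA_real_)
  if (ci) ci_b1 <- profile_ci_beta1(iv, beta0, beta1, loglik, conf_level)
  structure(list(beta0 = beta0, beta1 = beta1, loglik = loglik,
                 ci_beta1 = ci_b1, n_events = n_events,
                 n_censored = n_censored, null_model = FALSE,
                 scenario = exposure$scenario, boundary = boundary),
            class = "establishment_fit")
}

profile_loglik_beta1 <- function(iv, beta1, b0_start) {
  o <- optimize(function(b0) -.loglik_intervals(b0, beta1, iv),
                c(b0_start - 15, b0_start + 15), tol = 1e-10)
  -o$objective
}

profile_ci_beta1 <- function(iv, beta0, beta1, loglik, conf_level = 0.95) {
  cut <- qchisq(conf_level, 1) / 2
  f <- function(b1) profile_loglik_beta1(iv, b1, beta0) - (loglik - cut)
  # step out from the MLE until the profile drops below the cutoff
  find_bound <- function(dir) {
    step <- max(abs(beta1), 1e-4)
    b <- beta1
    for (k in 1:60) {
      b_new <- beta1 + dir * step
      if (f(b_new) < 0)
        return(uniroot(f, sort(c(b, b_new)), tol = 1e-10)$root)
      b <- b_new
      step <- step * 2
    }
    dir * Inf   # profile never drops: boundary interval
  }
  c(find_bound(-1), find_bound(1))
}

#' Likelihood-ratio test of an establishment fit against its null
#'
#' @param full an [establishment_fit()] with free `beta1`.
#' @param null the intercept-only fit on the same survey.
#' @return List of class `establishment_lrt` with `statistic`
#'   (`2 * (ll_full - ll_null)`), `df = 1` and the upper-tail
#'   chi-square(1) `p_value`.
#' @export
establishment_lrt <- function(full, null) {
  stat <- max(0, 2 * (full$loglik - null$loglik))
  structure(list(statistic = stat, df = 1L,
                 p_value = pchisq(stat, 1, lower.tail = FALSE)),
            class = "establishment_lrt")
}

#' Fit and rank dispersal scenarios by likelihood-ratio statistic
#'
#' Fits the establishment model once per exposure scenario plus a shared
#' intercept-only null, and ranks scenarios by the LRT statistic (all
#' scenario models share the same number of parameters, so LRT magnitude
#' ranks explanatory power).
#'
#' @param exposures named list of [exposure_series()], one per scenario.
#' @param survey a [survey_table()].
#' @param ci compute profile CIs (slower).
#' @return A data.frame of class `scenario_comparison`: one row per
#'   scenario with effect estimate, CI, log-likelihood, LRT statistic and
#'   p-value, ranked by LRT; the winner is flagged.
#' @export
compare_scenarios <- function(exposures, survey, ci = TRUE) {
  if (length(exposures) < 2 && is.null(names(exposures)))
    names(exposures) <- vapply(exposures, `[[`, "", "scenario")
  if (is.null(names(exposures)))
    names(exposures) <- vapply(exposures, `[[`, "", "scenario")
  null <- establishment_fit(exposures[[1]], survey, null_model = TRUE)
  rows <- list()
  fits <- list()
  for (nm in names(exposures)) {
    fit <- tryCatch(establishment_fit(exposures[[nm]], survey, ci = ci),
                    error = function(e) {
                      warning("scenario ", nm, " skipped: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) next
    lrt <- establishment_lrt(fit, null)
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(scenario = nm, beta1 = fit$beta1,
                             ci_lo = fit$ci_beta1[1], ci_hi = fit$ci_beta1[2],
                             loglik = fit$loglik, lrt = lrt$statistic,
                             p_value = lrt$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$lrt), ]
  out$winner <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "null") <- null
  class(out) <- c("scenario_comparison", "data.frame")
  out
}

# --- S3 methods ------------------------------------------------------------

#' @export
print.establishment_fit <- function(x, ...) {
  cat("Interval-censored Poisson establishment model",
      if (x$null_model) "(intercept-only null)" else
        paste0("(scenario: ", x$scenario, ")"), "\n")
  cat(sprintf("  beta0 (log baseline intensity) = %.4f\n", x$beta0))
  if (!x$null_model)
    cat(sprintf("  beta1 (effect per exposure unit) = %.6g  [95%% CI %.6g, %.6g]\n",
                x$beta1, x$ci_beta1[1], x$ci_beta1[2]))
  cat(sprintf("  log-likelihood = %.4f;  events = %d, censored = %d\n",
              x$loglik, x$n_events, x$n_censored))
  invisible(x)
}

#' @export
summary.establishment_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  baseline yearly colonization probability = %.4g\n",
              -expm1(-exp(object$beta0))))
  invisible(object)
}

#' @export
coef.establishment_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1)
}

#' @export
logLik.establishment_fit <- function(object, ...) {
  structure(object$loglik, df = if (object$null_model) 1L else 2L,
            class = "logLik")
}

#' @export
confint.establishment_fit <- function(object, parm = "beta1", level = 0.95, ...) {
  m <- matrix(object$ci_beta1, 1, 2,
              dimnames = list("beta1", paste0(c((1 - level) / 2,
                                                1 - (1 - level) / 2) * 100, " %")))
  m
}

#' Predicted yearly intensity or colonization probability
#'
#' @param object an [establishment_fit()].
#' @param exposure an [exposure_series()] to predict for.
#' @param type `"intensity"` (lambda) or `"prob"` (`1 - exp(-lambda)`).
#' @param ... unused.
#' @return Matrix sites x years.
#' @export
predict.establishment_fit <- function(object, exposure,
                                      type = c("intensity", "prob"), ...) {
  type <- match.arg(type)
  lam <- exp(object$beta0 + object$beta1 * exposure$x)
  if (type == "prob") -expm1(-lam) else lam
}

#' Simulate survey tables from a fitted establishment model
#'
#' @param object an [establishment_fit()].
#' @param nsim number of survey tables.
#' @param seed optional seed.
#' @param exposure an [exposure_series()].
#' @param survey_years years of the simulated annual surveys.
#' @param ... unused.
#' @return List of [survey_table()] of length `nsim`.
#' @export
simulate.establishment_fit <- function(object, nsim = 1, seed = NULL,
                                       exposure, survey_years = exposure$years,
                                       ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_survey(exposure, object$beta0, object$beta1, survey_years))
}

#' Martingale-type residuals of an establishment fit
#'
#' Per site: the event indicator minus the fitted cumulative intensity
#' accumulated over the site's observed (pre-detection) years.  Large
#' positive values flag sites colonized much earlier than their exposure
#' predicts; large negative values flag heavily exposed sites that were
#' never colonized.
#'
#' @param object an [establishment_fit()].
#' @param exposure,survey the data the model was fitted to.
#' @param ... unused.
#' @return Named numeric vector, one residual per site.
#' @export
residuals.establishment_fit <- function(object, exposure, survey, ...) {
  iv <- site_intervals(exposure, survey)
  vapply(iv, function(s) {
    lam <- exp(object$beta0 + object$beta1 * c(s$x_before, s$x_interval))
    as.numeric(s$event) - sum(lam)
  }, 0)
}

#' Plot an establishment fit
#'
#' Observed cumulative number of colonized sites by year against the
#' model's expected curve (sum over sites of their fitted colonization
#' probabilities).
#'
#' @param x an [establishment_fit()].
#' @param exposure,survey the data the model was fitted to.
#' @param ... passed to [plot()].
#' @return Invisibly, a data.frame of year, observed and expected counts.
#' @export
plot.establishment_fit <- function(x, exposure, survey, ...) {
  years <- sort(unique(survey$year))
  det <- detection_years(survey)
  obs <- vapply(years, function(y) sum(!is.na(det) & det <= y), 0)
  lam <- exp(x$beta0 + x$beta1 * exposure$x[unique(survey$site_id), ,
                                            drop = FALSE])
  surv <- t(apply(lam, 1, function(v) exp(-cumsum(v))))
  expd <- colSums(1 - surv[, match(years, exposure$years), drop = FALSE])
  plot(years, obs, type = "s", xlab = "year",
       ylab = "colonized sites (cumulative)", ...)
  graphics::lines(years, expd, lty = 2)
  graphics::legend("topleft", legend = c("observed", "expected"),
                   lty = c(1, 2), bty = "n")
  invisible(data.frame(year = years, observed = obs, expected = expd))
}

#' @export
print.establishment_lrt <- function(x, ...) {
  cat(sprintf("LRT statistic = %.4f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Dispersal-scenario comparison (LRT vs shared intercept-only null)\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
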