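#' Resistance of an ecological attribute to land use
#'
#' Fraction of an attribute retained under active agriculture relative to
#' the old-growth reference, expressed through the negative exponential of
#' the absolute log-ratio: `100 * exp(-|ln(psi0 / psi_ref)|)`. The measure
#' is bounded in `[0, 100]`, equals 100 when the active level matches the
#' reference, and treats levels above the reference as a disturbance effect
#' (a ratio of 1.3 scores 77, not 100). Equivalently it is
#' `100 * min(r, 1/r)` with `r = psi0 / psi_ref`.
#'
#' @param psi0 Active-plot central value (>= 0).
#' @param psi_ref Old-growth reference central value (> 0).
#' @return Resistance as a percentage in `[0, 100]`.
#' @export
resistance <- function(psi0, psi_ref) {
  if (any(!is.finite(psi_ref)) || any(psi_ref <= 0)) {
    abort("psi_ref must be positive and finite.",
          class = "regrow_undefined_input")
  }
  if (any(!is.finite(psi0)) || any(psi0 < 0)) {
    abort("psi0 must be non-negative and finite.",
          class = "regrow_undefined_input")
  }
  ifelse(psi0 == 0, 0, 100 * exp(-abs(log(psi0 / psi_ref))))
}

# negative-exponential recovery trajectory
recovery_curve <- function(t, lambda, psi0, psi_ref) {
  psi0 + (psi_ref - psi0) * (1 - exp(-lambda * t))
}

#' Fit the negative-exponential recovery model to one legacy's series
#'
#' Fits `psi(t) = psi0 + (psi_ref - psi0) * (1 - exp(-lambda * t))` to the
#' `(age, value)` points of one land-use legacy (active plots at `t = 0`
#' together with the recovering secondary plots), with `psi0` and `psi_ref`
#' held fixed at the series' central values so the curve interpolates
#' between the active-plot level and the old-growth reference. The single
#' free parameter `lambda` (the return rate, per year) is estimated by
#' bounded least squares: a coarse bracketing grid over `[0, 10]` followed
#' by Brent minimisation of the sum of squared errors.
#'
#' The standard error comes from the asymptotic (Gauss-Newton) covariance
#' of the one-parameter fit; significance is a two-sided Wald test of
#' `lambda = 0`.
#'
#' @param series A tibble from [metric_series()] (or one legacy's subset of
#'   it, with the `centers` attribute intact).
#' @param legacy Which legacy to fit; may be omitted when `series` holds a
#'   single legacy.
#' @param lambda_bounds Search interval for `lambda` (per year).
#' @param alpha Significance level for the Wald test of `lambda = 0`.
#' @param free_psi0 If `TRUE`, `psi0` is estimated from the trajectory
#'   instead of being fixed at the active-plot center (sensitivity switch;
#'   the default keeps it fixed so resistance and the curve share one
#'   `psi0`).
#' @return An object of class `recovery_fit`: a list with elements
#'   `lambda`, `lambda_se`, `lambda_p`, `lambda_significant`, `psi0`,
#'   `psi_ref`, `center_rule`, `r_squared`, `sse`, `n_points`, `metric`,
#'   `legacy` and the fitted `data`.
#' @export
fit_recovery <- function(series, legacy = NULL,
                         lambda_bounds = c(0, 10), alpha = 0.05,
                         free_psi0 = FALSE) {
  centers <- series_centers(series)
  if (is.null(centers)) {
    abort("series lacks its `centers` attribute; build it with metric_series().",
          class = "regrow_validation_error")
  }
  if (is.null(legacy)) {
    legacy <- unique(series$legacy)
    if (length(legacy) != 1) {
      abort("series holds several legacies; pass `legacy` explicitly.",
            class = "regrow_validation_error")
    }
  }
  pts <- dplyr::filter(series, .data$legacy == !!legacy)
  ctr <- dplyr::filter(centers, .data$legacy == !!legacy)
  if (nrow(ctr) != 1 || !is.finite(ctr$psi0) || !is.finite(ctr$psi_ref)) {
    abort(paste0("psi0/psi_ref undefined for legacy ", legacy),
          class = "regrow_validation_error")
  }
  if (nrow(pts) < 3) {
    abort("At least 3 points are required to fit the recovery model.",
          class = "regrow_fit_error")
  }
  t <- pts$age_years
  v <- pts$value
  psi_ref <- ctr$psi_ref
  psi0 <- ctr$psi0

  if (free_psi0) {
    # profile psi0 out: for fixed lambda the optimal psi0 is linear LS
    sse_at <- function(lambda) {
      g <- 1 - exp(-lambda * t)
      # v = psi0 * (1 - g) + psi_ref * g + e
      resp <- v - psi_ref * g
      x <- 1 - g
      b <- sum(resp * x) / sum(x^2)
      sum((resp - b * x)^2)
    }
  } else {
    sse_at <- function(lambda) {
      sum((v - recovery_curve(t, lambda, psi0, psi_ref))^2)
    }
  }

  if (sd(v) == 0 && v[1] == psi0) {
    lambda_hat <- 0
    sse <- 0
  } else {
    grid <- unique(c(lambda_bounds[1],
                     10^seq(-4, log10(max(lambda_bounds[2], 1e-3)), length.out = 121)))
    grid <- grid[grid >= lambda_bounds[1] & grid <= lambda_bounds[2]]
    sse_grid <- purrr::map_dbl(grid, sse_at)
    i <- which.min(sse_grid)
    lo <- grid[max(i - 1, 1)]
    hi <- grid[min(i + 1, length(grid))]
    if (lo == hi) {
      lambda_hat <- lo
    } else {
      opt <- optimize(sse_at, interval = c(lo, hi), tol = 1e-12)
      lambda_hat <- if (opt$objective <= sse_grid[i]) opt$minimum else grid[i]
    }
    if (sse_at(lambda_bounds[1]) <= sse_at(lambda_hat)) {
      lambda_hat <- lambda_bounds[1]
    }
    sse <- sse_at(lambda_hat)
  }

  if (free_psi0) {
    g <- 1 - exp(-lambda_hat * t)
    resp <- v - psi_ref * g
    x <- 1 - g
    psi0 <- sum(resp * x) / sum(x^2)
  }

  n <- length(v)
  jac <- (psi_ref - psi0) * t * exp(-lambda_hat * t)
  jtj <- sum(jac^2)
  sigma2 <- sse / max(n - 1, 1)
  lambda_se <- if (jtj > 0) sqrt(sigma2 / jtj) else NA_real_
  lambda_p <- if (is.finite(lambda_se) && lambda_se > 0) {
    2 * pt(-abs(lambda_hat / lambda_se), df = n - 1)
  } else {
    NA_real_
  }
  sst <- sum((v - mean(v))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_

  structure(
    list(
      lambda = lambda_hat,
      lambda_se = lambda_se,
      lambda_p = lambda_p,
      lambda_significant = isTRUE(is.finite(lambda_p) && lambda_p < alpha),
      psi0 = psi0,
      psi_ref = psi_ref,
      center_rule = ctr$center_rule,
      r_squared = r2,
      sse = sse,
      n_points = n,
      metric = if (nrow(pts) > 0) pts$metric[1] else NA_character_,
      legacy = legacy,
      free_psi0 = free_psi0,
      data = pts
    ),
    class = "recovery_fit"
  )
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat("Negative-exponential recovery fit (", x$metric, ", ", x$legacy,
      " legacy)\n", sep = "")
  cat(sprintf("  lambda    = %.5g per year (SE %.3g, p = %.3g%s)\n",
              x$lambda, x$lambda_se, x$lambda_p,
              if (isTRUE(x$lambda_significant)) ", significant" else ""))
  cat(sprintf("  psi0      = %.5g   psi_ref = %.5g  (%s)\n",
              x$psi0, x$psi_ref, x$center_rule))
  cat(sprintf("  R-squared = %.3f on %d plots\n", x$r_squared, x$n_points))
  invisible(x)
}

#' Predicted trajectory values from a recovery fit
#'
#' @param object A `recovery_fit`.
#' @param t Times (years since abandonment) at which to evaluate the curve.
#' @param ... Unused.
#' @return Numeric vector `psi(t)`.
#' @export
predict.recovery_fit <- function(object, t = NULL, ...) {
  t <- t %||% object$data$age_years
  recovery_curve(t, object$lambda, object$psi0, object$psi_ref)
}

#' Time to recover to within 10 percent of the reference
#'
#' Solves the fitted trajectory for `psi(t) = 0.9 * psi_ref` (recovery from
#' below) or `1.1 * psi_ref` (from above), which collapses to
#' `T = -ln(0.1 * psi_ref / |psi_ref - psi0|) / lambda`. A resistance above
#' 90\% means the community already sits inside the tolerance band: the
#' recovery time is 0 and no return rate is defined. A zero return rate
#' with resistance at or below 90\% yields an infinite time (an
#' arrested-recovery candidate, resolved by [classify_recovery()]).
#'
#' @param resistance_pct Resistance in percent.
#' @param lambda Return rate per year (may be `NA` when
#'   `resistance_pct > 90`).
#' @param psi0,psi_ref The centers the fit was conditioned on.
#' @return Years (0 for instantaneous recovery, `Inf` when arrested).
#' @export
recovery_time <- function(resistance_pct, lambda, psi0, psi_ref) {
  if (resistance_pct > 90) {
    return(0)
  }
  if (!is.finite(lambda) || lambda < 0) {
    abort("lambda must be a non-negative number when resistance <= 90%.",
          class = "regrow_undefined_input")
  }
  gap <- abs(psi_ref - psi0)
  if (gap <= 0.1 * psi_ref) {
    # only reachable when the mean rule leaves resistance <= 90 despite a
    # within-tolerance gap
    warn("Gap |psi_ref - psi0| within the 10% tolerance; recovery time set to 0.")
    return(0)
  }
  if (lambda == 0) {
    return(Inf)
  }
  -log(0.1 * psi_ref / gap) / lambda
}

#' Relative recovery at a fixed horizon
#'
#' Evaluates the fitted trajectory at `t_eval` years and converts the
#' modelled level to the same bounded similarity scale as resistance:
#' `100 * exp(-|ln(psi(t) / psi_ref)|)`. With `lambda = 0` this equals the
#' resistance itself.
#'
#' @param fit A `recovery_fit`, or a list with elements `lambda`, `psi0`,
#'   `psi_ref`.
#' @param t_eval Evaluation horizon in years (default 30).
#' @return Percentage in `[0, 100]`.
#' @export
relative_recovery_at <- function(fit, t_eval = 30) {
  psi_t <- recovery_curve(t_eval, fit$lambda, fit$psi0, fit$psi_ref)
  resistance(max(psi_t, 0), fit$psi_ref)
}

#' Classify a draft recovery time
#'
#' Recovery times beyond `cap_years` are resolved against the spread of the
#' raw data: when the mean +/- SD intervals of the active and old-growth
#' plot values overlap, the huge time is treated as an artefact of data
#' spread and zeroed; when they do not overlap the community is classified
#' as arrested and the large value kept (reported as `">cap"`). SD is the
#' sample standard deviation (n - 1 denominator).
#'
#' @param time_years Draft recovery time (may be `Inf`).
#' @param active_values Metric values of the legacy's active plots.
#' @param og_values Metric values of the old-growth plots.
#' @param cap_years Cap above which the artefact/arrested rule applies.
#' @param instant Set `TRUE` when the instant-recovery rule already fired.
#' @return A list with `classification` (`normal`, `instant`,
#'   `artefact_zeroed` or `arrested`) and `time_years` after the rule.
#' @export
classify_recovery <- function(time_years, active_values, og_values,
                              cap_years = 300, instant = FALSE) {
  if (instant) {
    return(list(classification = "instant", time_years = 0))
  }
  if (time_years <= cap_years) {
    return(list(classification = "normal", time_years = time_years))
  }
  a_lo <- mean(active_values) - sd(active_values)
  a_hi <- mean(active_values) + sd(active_values)
  o_lo <- mean(og_values) - sd(og_values)
  o_hi <- mean(og_values) + sd(og_values)
  if (max(a_lo, o_lo) <= min(a_hi, o_hi)) {
    list(classification = "artefact_zeroed", time_years = 0)
  } else {
    list(classification = "arrested", time_years = time_years)
  }
}

#' Resilience summary for one taxon
#'
#' Runs the full per-taxon decomposition for one metric: per-plot series and
#' centers, resistance, the negative-exponential fit per legacy, recovery
#' time with the instant/artefact/arrested rules, and relative recovery at
#' the evaluation horizon.
#'
#' When resistance exceeds 90\% the community is considered undisturbed or
#' instantaneously recolonised: recovery time is 0 and no return rate is
#' estimated.
#'
#' @param abundance Wide abundance tibble.
#' @param plots Validated plot table.
#' @param metric Metric name (see [metric_series()]).
#' @param taxon Taxon label carried into the output.
#' @param legacies Legacies to summarise.
#' @param cap_years Recovery-time cap for the artefact/arrested rule.
#' @param t_eval Horizon (years) for relative recovery.
#' @param alpha Significance level for the return-rate Wald test.
#' @return A tibble with one row per legacy: centers, resistance (%),
#'   return rate (per year) with SE/p/significance, R^2, recovery time,
#'   classification and relative recovery (%).
#' @export
summarize_resilience <- function(abundance, plots, metric,
                                 taxon = attr(abundance, "taxon") %||% "taxon",
                                 legacies = LEGACIES,
                                 cap_years = 300, t_eval = 30, alpha = 0.05) {
  series <- metric_series(abundance, plots, metric, legacies = legacies)
  og_values <- attr(series, "og_values", exact = TRUE)$value
  purrr::map_dfr(legacies, function(leg) {
    summarize_legacy(series, leg, og_values, taxon, metric,
                     cap_years, t_eval, alpha)
  })
}

summarize_legacy <- function(series, leg, og_values, taxon, metric,
                             cap_years, t_eval, alpha) {
  ctr <- dplyr::filter(series_centers(series), .data$legacy == leg)
  pts <- dplyr::filter(series, .data$legacy == leg)
  res_pct <- resistance(ctr$psi0, ctr$psi_ref)
  active_values <- pts$value[pts$age_years %in% 0]

  if (res_pct > 90) {
    cls <- classify_recovery(0, active_values, og_values,
                             cap_years = cap_years, instant = TRUE)
    return(tibble::tibble(
      taxon = taxon, metric = metric, legacy = leg,
      n_points = nrow(pts),
      center_rule = ctr$center_rule,
      psi0 = ctr$psi0, psi_ref = ctr$psi_ref,
      resistance_pct = res_pct,
      return_rate = NA_real_, return_rate_se = NA_real_,
      return_rate_p = NA_real_, return_rate_significant = NA,
      r_squared = NA_real_,
      recovery_time_years = cls$time_years,
      classification = cls$classification,
      relative_recovery_pct = res_pct,
      t_eval = t_eval
    ))
  }

  fit <- fit_recovery(series, legacy = leg, alpha = alpha)
  t_draft <- recovery_time(res_pct, fit$lambda, fit$psi0, fit$psi_ref)
  cls <- classify_recovery(t_draft, active_values, og_values,
                           cap_years = cap_years)
  tibble::tibble(
    taxon = taxon, metric = metric, legacy = leg,
    n_points = fit$n_points,
    center_rule = ctr$center_rule,
    psi0 = fit$psi0, psi_ref = fit$psi_ref,
    resistance_pct = res_pct,
    return_rate = fit$lambda, return_rate_se = fit$lambda_se,
    return_rate_p = fit$lambda_p,
    return_rate_significant = fit$lambda_significant,
    r_squared = fit$r_squared,
    recovery_time_years = cls$time_years,
    classification = cls$classification,
    relative_recovery_pct = relative_recovery_at(fit, t_eval),
    t_eval = t_eval
  )
}
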