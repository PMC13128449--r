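#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a recovery fit
#'
#' @param x A `recovery_fit`.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` for the return rate.
#' @export
tidy.recovery_fit <- function(x, ...) {
  tibble::tibble(
    term = "lambda",
    estimate = x$lambda,
    std.error = x$lambda_se,
    statistic = if (is.finite(x$lambda_se) && x$lambda_se > 0) {
      x$lambda / x$lambda_se
    } else {
      NA_real_
    },
    p.value = x$lambda_p
  )
}

#' One-row model summary of a recovery fit
#'
#' @param x A `recovery_fit`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `sigma`, `nobs`, `psi0`, `psi_ref`,
#'   `center_rule`.
#' @export
glance.recovery_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = sqrt(x$sse / max(x$n_points - 1, 1)),
    nobs = x$n_points,
    psi0 = x$psi0,
    psi_ref = x$psi_ref,
    center_rule = x$center_rule
  )
}

#' Observed points with fitted trajectory values
#'
#' @param x A `recovery_fit`.
#' @param ... Unused.
#' @return The fitted points with `.fitted` and `.resid` columns.
#' @export
augment.recovery_fit <- function(x, ...) {
  dplyr::mutate(
    x$data,
    .fitted = predict(x, x$data$age_years),
    .resid = .data$value - .data$.fitted
  )
}
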