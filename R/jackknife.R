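#' Leave-one-plot-out jackknife of the resilience decomposition
#'
#' Deletes, in turn, each plot eligible for one legacy's analysis — its
#' active and secondary plots plus every old-growth plot (old growth is
#' shared by both legacies) — and reruns the entire pipeline on the reduced
#' plot set: the per-plot metric, the similarity-to-reference values, the
#' centers `psi0`/`psi_ref`, the fit and every downstream statistic are all
#' recomputed from scratch. Replicates rendered degenerate by the deletion
#' (for example no active plot left) are excluded and recorded.
#'
#' @inheritParams summarize_resilience
#' @param legacy The legacy to jackknife.
#' @return An object of class `resilience_jackknife`: a list with
#'   `replicates` (summary rows, one per deleted plot, with a
#'   `deleted_plot` column), `estimate` (the full-data summary row), `n`,
#'   `excluded` (tibble of skipped deletions and reasons), `metric`,
#'   `legacy`, `cap_years` and `t_eval`.
#' @export
jackknife_resilience <- function(abundance, plots, metric, legacy,
                                 taxon = attr(abundance, "taxon") %||% "taxon",
                                 cap_years = 300, t_eval = 30, alpha = 0.05) {
  m_ids <- colnames(abundance_matrix(abundance))
  plots <- dplyr::filter(plots, .data$plot_id %in% m_ids)
  eligible <- plots$plot_id[
    plots$legacy == legacy | plots$category == "old_growth"
  ]
  estimate <- summarize_resilience(
    abundance, plots, metric, taxon = taxon, legacies = legacy,
    cap_years = cap_years, t_eval = t_eval, alpha = alpha
  )
  reps <- purrr::map(eligible, function(drop_id) {
    reduced <- dplyr::filter(plots, .data$plot_id != drop_id)
    tryCatch(
      dplyr::mutate(
        suppressMessages(summarize_resilience(
          abundance, reduced, metric, taxon = taxon, legacies = legacy,
          cap_years = cap_years, t_eval = t_eval, alpha = alpha
        )),
        deleted_plot = drop_id
      ),
      error = function(e) tibble::tibble(
        deleted_plot = drop_id, reason = conditionMessage(e)
      )
    )
  })
  ok <- purrr::map_lgl(reps, function(r) "resistance_pct" %in% names(r))
  excluded <- dplyr::bind_rows(reps[!ok])
  if (nrow(excluded) > 0) {
    inform(paste0(
      "Jackknife: ", nrow(excluded), " replicate(s) excluded (",
      paste(unique(excluded$reason), collapse = "; "), ")"
    ))
  }
  structure(
    list(
      replicates = dplyr::bind_rows(reps[ok]),
      estimate = estimate,
      n = length(eligible),
      excluded = excluded,
      metric = metric, legacy = legacy, taxon = taxon,
      cap_years = cap_years, t_eval = t_eval
    ),
    class = "resilience_jackknife"
  )
}

#' @export
print.resilience_jackknife <- function(x, ...) {
  cat("Jackknife ensemble (", x$taxon, ", ", x$metric, ", ", x$legacy,
      " legacy): ", nrow(x$replicates), "/", x$n, " replicates\n", sep = "")
  print(ci_from_ensemble(x))
  invisible(x)
}

#' Percentile confidence intervals from a jackknife ensemble
#'
#' Computes, for each resilience statistic, the interval containing the
#' central `level` share of the leave-one-out replicates (percentile
#' interval with linear interpolation between order statistics,
#' [stats::quantile()] type 7). The return-rate interval uses only
#' replicates where a rate is defined (the instant-recovery rule yields
#' none); the count of such replicates is reported. Infinite recovery
#' times (arrested replicates) propagate into an infinite upper bound,
#' rendered as `">cap"` in formatted tables.
#'
#' @param ensemble A `resilience_jackknife`.
#' @param level Interval level (default 0.95).
#' @return Tibble `statistic`, `estimate`, `lower`, `upper`, `n_used`.
#' @export
ci_from_ensemble <- function(ensemble, level = 0.95) {
  reps <- ensemble$replicates
  stats_cols <- c("resistance_pct", "return_rate",
                  "recovery_time_years", "relative_recovery_pct")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  purrr::map_dfr(stats_cols, function(colname) {
    x <- reps[[colname]]
    x <- x[!is.na(x)]
    est <- ensemble$estimate[[colname]]
    if (length(x) < 2) {
      return(tibble::tibble(
        statistic = colname, estimate = est,
        lower = NA_real_, upper = NA_real_, n_used = length(x)
      ))
    }
    if (any(is.infinite(x))) {
      # quantile() cannot interpolate with Inf; order statistics still work
      xs <- sort(x)
      qs <- purrr::map_dbl(probs, function(p) {
        h <- (length(xs) - 1) * p
        lo <- xs[floor(h) + 1]
        hi <- xs[ceiling(h) + 1]
        if (is.infinite(lo) || is.infinite(hi)) {
          if (h - floor(h) == 0) lo else hi
        } else {
          lo + (h - floor(h)) * (hi - lo)
        }
      })
    } else {
      qs <- unname(quantile(x, probs = probs, type = 7))
    }
    tibble::tibble(
      statistic = colname, estimate = est,
      lower = qs[1], upper = qs[2], n_used = length(x)
    )
  })
}

#' Pointwise jackknife envelope of the fitted trajectories
#'
#' Rebuilds each replicate's fitted curve from its `psi0`, `psi_ref` and
#' return rate and returns the pointwise percentile envelope on a time
#' grid, together with the full-data curve.
#'
#' @param ensemble A `resilience_jackknife`.
#' @param times Time grid in years.
#' @param level Envelope level.
#' @return Tibble `t`, `fit`, `lower`, `upper`.
#' @export
jackknife_band <- function(ensemble, times = seq(0, 40, by = 0.5),
                           level = 0.95) {
  reps <- dplyr::filter(ensemble$replicates, !is.na(.data$return_rate))
  est <- ensemble$estimate
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  fit_curve <- if (!is.na(est$return_rate)) {
    recovery_curve(times, est$return_rate, est$psi0, est$psi_ref)
  } else {
    rep(est$psi_ref, length(times))
  }
  if (nrow(reps) < 2) {
    return(tibble::tibble(
      t = times, fit = fit_curve, lower = NA_real_, upper = NA_real_
    ))
  }
  curves <- purrr::pmap(
    list(reps$return_rate, reps$psi0, reps$psi_ref),
    function(l, p0, pr) recovery_curve(times, l, p0, pr)
  )
  cm <- do.call(rbind, curves)
  env <- apply(cm, 2, quantile, probs = probs, type = 7)
  tibble::tibble(
    t = times, fit = fit_curve, lower = env[1, ], upper = env[2, ]
  )
}
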