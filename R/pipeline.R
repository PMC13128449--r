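#' Run the full resilience pipeline and write its artifact set
#'
#' Wires the stages end to end for a set of taxa sharing one plot design:
#' validation, per-plot metrics and similarity-to-reference series,
#' negative-exponential fits per legacy, the resistance / return-rate /
#' recovery-time decomposition, optional leave-one-plot-out jackknife CIs,
#' cross-taxon comparative statistics, and a Table-style summary TSV plus
#' a machine-readable JSON manifest recording inputs, configuration,
#' package version and seed.
#'
#' Unknown metric names fail validation before any computation starts.
#'
#' @param plots Validated plot table (or a path to one).
#' @param abundances Named list of wide abundance tibbles (or paths), one
#'   per taxon.
#' @param out_dir Output directory; created if needed. `NULL` skips all
#'   file output.
#' @param metrics Metric names to analyse (see [metric_series()]).
#' @param legacies Legacies to analyse.
#' @param cap_years,t_eval,alpha Passed to [summarize_resilience()].
#' @param jackknife Compute jackknife CIs (slower).
#' @param comparative Run cross-taxon statistics (needs enough taxa).
#' @param seed Seed recorded in the manifest and used for the forest.
#' @return (Invisibly) a list with `summary`, `pairwise`, `jackknife_ci`,
#'   `comparative` tibbles and the `manifest` list.
#' @export
run_pipeline <- function(plots, abundances, out_dir = NULL,
                         metrics = c("abundance", "hill_q1", "bray_curtis_sim"),
                         legacies = LEGACIES,
                         cap_years = 300, t_eval = 30, alpha = 0.05,
                         jackknife = TRUE, comparative = TRUE, seed = 1) {
  unknown <- setdiff(metrics, METRIC_NAMES)
  if (length(unknown) > 0) {
    abort(paste0("Unknown metric(s): ", paste(unknown, collapse = ", ")),
          class = "regrow_validation_error")
  }
  if (is.character(plots)) plots <- read_plot_table(plots)
  plots <- validate_plot_table(plots)
  if (is.null(names(abundances)) || any(names(abundances) == "")) {
    abort("`abundances` must be a named list (one element per taxon).",
          class = "regrow_validation_error")
  }
  abundances <- purrr::imap(abundances, function(a, nm) {
    if (is.character(a)) read_abundance_matrix(a, plots, taxon = nm)
    else as_abundance_table(a, plots, taxon = nm)
  })

  grid <- tidyr::expand_grid(taxon = names(abundances), metric = metrics)
  summaries <- purrr::map2_dfr(grid$taxon, grid$metric, function(tx, me) {
    suppressMessages(summarize_resilience(
      abundances[[tx]], plots, me, taxon = tx, legacies = legacies,
      cap_years = cap_years, t_eval = t_eval, alpha = alpha
    ))
  })

  pairwise <- purrr::map_dfr(
    intersect(metrics, SIMILARITY_METRICS),
    function(me) purrr::imap_dfr(abundances, function(a, nm) {
      dplyr::mutate(pairwise_similarity(a, me), taxon = nm, .before = 1)
    })
  )

  jk_ci <- NULL
  if (jackknife) {
    jk_grid <- tidyr::expand_grid(
      taxon = names(abundances), metric = metrics, legacy = legacies
    )
    jk_ci <- purrr::pmap_dfr(jk_grid, function(taxon, metric, legacy) {
      ens <- suppressMessages(jackknife_resilience(
        abundances[[taxon]], plots, metric, legacy, taxon = taxon,
        cap_years = cap_years, t_eval = t_eval, alpha = alpha
      ))
      dplyr::mutate(ci_from_ensemble(ens),
                    taxon = taxon, metric = metric, legacy = legacy,
                    .before = 1)
    })
    summaries <- attach_ci(summaries, jk_ci)
  }

  comp <- NULL
  if (comparative) {
    comp <- purrr::map_dfr(legacies, function(leg) {
      rows <- dplyr::filter(summaries, .data$legacy == leg)
      dplyr::mutate(importance_rf(rows, seed = seed),
                    legacy = leg, .before = 1)
    })
  }

  manifest <- list(
    package = "regrow",
    version = as.character(packageVersion("regrow")),
    r_version = as.character(getRversion()),
    seed = seed,
    metrics = metrics, legacies = legacies,
    cap_years = cap_years, t_eval = t_eval, alpha = alpha,
    jackknife = jackknife,
    n_plots = nrow(plots),
    taxa = names(abundances),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_summary_table(summaries, file.path(out_dir, "summary.tsv"),
                        cap_years = cap_years)
    if (nrow(pairwise) > 0) {
      readr::write_tsv(pairwise, file.path(out_dir, "pairwise_similarity.tsv"))
    }
    if (!is.null(jk_ci)) {
      readr::write_tsv(jk_ci, file.path(out_dir, "jackknife_ci.tsv"))
    }
    if (!is.null(comp)) {
      readr::write_tsv(comp, file.path(out_dir, "comparative.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(
    summary = summaries, pairwise = pairwise, jackknife_ci = jk_ci,
    comparative = comp, manifest = manifest
  ))
}

# fold jackknife CI rows into lo/hi columns on the summary table
attach_ci <- function(summaries, jk_ci) {
  wide <- tidyr::pivot_wider(
    jk_ci,
    id_cols = c("taxon", "metric", "legacy"),
    names_from = "statistic",
    values_from = c("lower", "upper")
  )
  ren <- c(
    resistance_pct_lo = "lower_resistance_pct",
    resistance_pct_hi = "upper_resistance_pct",
    return_rate_lo = "lower_return_rate",
    return_rate_hi = "upper_return_rate",
    recovery_time_years_lo = "lower_recovery_time_years",
    recovery_time_years_hi = "upper_recovery_time_years",
    relative_recovery_pct_lo = "lower_relative_recovery_pct",
    relative_recovery_pct_hi = "upper_relative_recovery_pct"
  )
  wide <- dplyr::rename(wide, dplyr::any_of(ren))
  dplyr::left_join(summaries, wide, by = c("taxon", "metric", "legacy"))
}
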