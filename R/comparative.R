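#' Random-forest importance of resistance versus return rate
#'
#' Fits a seeded random-forest regression of recovery time on resistance
#' and return rate across taxa and reports impurity (variance-reduction)
#' importances together with their ratio. Taxa whose resistance exceeds
#' 90\% carry no return rate (the instant-recovery rule) and are excluded,
#' as are rows with an undefined or infinite recovery time; both counts are
#' reported.
#'
#' @param data Tibble with columns `resistance_pct`, `return_rate`,
#'   `recovery_time_years` (one row per taxon x metric x legacy).
#' @param seed Integer seed for the forest.
#' @param num_trees Trees in the forest.
#' @param min_rows Minimum usable rows; below it the analysis is skipped.
#' @return Tibble `predictor`, `importance`, `ratio_return_to_resistance`,
#'   `n_taxa`, `excluded_instant`, `excluded_undefined`, `skipped`.
#' @export
importance_rf <- function(data, seed = 1, num_trees = 500, min_rows = 5) {
  data <- tibble::as_tibble(data)
  instant <- data$resistance_pct > 90 | is.na(data$return_rate)
  usable <- !instant & is.finite(data$recovery_time_years)
  excluded_instant <- sum(instant)
  excluded_undefined <- sum(!instant & !usable)
  rows <- data[usable, , drop = FALSE]
  base <- tibble::tibble(
    predictor = c("resistance", "return_rate"),
    importance = NA_real_,
    ratio_return_to_resistance = NA_real_,
    n_taxa = nrow(rows),
    excluded_instant = excluded_instant,
    excluded_undefined = excluded_undefined
  )
  if (nrow(rows) < min_rows) {
    return(dplyr::mutate(base, skipped = TRUE))
  }
  fit <- ranger::ranger(
    recovery_time_years ~ resistance_pct + return_rate,
    data = rows[, c("resistance_pct", "return_rate", "recovery_time_years")],
    num.trees = num_trees, importance = "impurity", seed = seed
  )
  imp <- fit$variable.importance
  dplyr::mutate(
    base,
    importance = unname(imp[c("resistance_pct", "return_rate")]),
    ratio_return_to_resistance =
      unname(imp["return_rate"] / imp["resistance_pct"]),
    skipped = FALSE
  )
}

#' Spearman rank correlation between resistance and return rate
#'
#' Two-sided Spearman correlation with midranks for ties; rows without a
#' defined return rate (instant recovery) are excluded and counted.
#'
#' @param data Tibble with columns `resistance_pct` and `return_rate`.
#' @return Tibble `rho`, `p_value`, `n`, `n_excluded`.
#' @export
spearman_resistance_vs_return <- function(data) {
  data <- tibble::as_tibble(data)
  ok <- is.finite(data$resistance_pct) & is.finite(data$return_rate)
  n_excluded <- sum(!ok)
  rows <- data[ok, ]
  if (nrow(rows) < 3) {
    abort("At least 3 taxa with defined resistance and return rate required.",
          class = "regrow_validation_error")
  }
  ct <- suppressWarnings(cor.test(
    rows$resistance_pct, rows$return_rate,
    method = "spearman", exact = FALSE
  ))
  tibble::tibble(
    rho = unname(ct$estimate), p_value = ct$p.value,
    n = nrow(rows), n_excluded = n_excluded
  )
}

#' Wilcoxon signed-rank test for paired recovery statistics
#'
#' Compares two paired vectors (for example recovery times of abundance
#' versus composition across taxa). Zero differences are dropped before
#' ranking (the standard signed-rank convention); the reported `V` is the
#' sum of ranks of positive differences. P-values use exact enumeration
#' when 10 or fewer nonzero untied pairs remain and the normal
#' approximation with continuity correction otherwise.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return Tibble `V`, `p_value`, `n_pairs` (nonzero pairs used),
#'   `n_dropped`, `defined`.
#' @export
wilcoxon_paired <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  keep <- is.finite(d) & d != 0
  n_dropped <- sum(!keep)
  d <- d[keep]
  if (length(d) == 0) {
    return(tibble::tibble(
      V = NA_real_, p_value = NA_real_, n_pairs = 0,
      n_dropped = n_dropped, defined = FALSE
    ))
  }
  use_exact <- length(d) <= 10 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(wilcox.test(
    d, mu = 0, paired = FALSE, exact = use_exact, correct = TRUE
  ))
  tibble::tibble(
    V = unname(wt$statistic), p_value = wt$p.value,
    n_pairs = length(d), n_dropped = n_dropped, defined = TRUE
  )
}

#' Kruskal-Wallis tests across groupings with FDR control
#'
#' Runs one Kruskal-Wallis rank test per declared test (for example each
#' grouping x metric x legacy combination) and adjusts the p-values across
#' the whole family with the Benjamini-Hochberg false-discovery-rate
#' procedure. Tests whose grouping has fewer than two non-empty groups are
#' skipped and recorded.
#'
#' @param data Long tibble with columns `test_id`, `value`, `group`.
#' @return Tibble `test_id`, `statistic`, `df`, `p_value`, `p_adjusted`,
#'   `n_groups`, `n`, `skipped`.
#' @export
kruskal_fdr <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("test_id", "value", "group") %in% names(data)))
  out <- purrr::map_dfr(unique(data$test_id), function(id) {
    rows <- data[data$test_id == id & is.finite(data$value), ]
    groups <- unique(rows$group)
    if (length(groups) < 2) {
      return(tibble::tibble(
        test_id = id, statistic = NA_real_, df = NA_real_,
        p_value = NA_real_, n_groups = length(groups),
        n = nrow(rows), skipped = TRUE
      ))
    }
    if (length(unique(rows$value)) == 1) {
      # every observation tied: no rank variance to partition
      return(tibble::tibble(
        test_id = id, statistic = 0, df = length(groups) - 1,
        p_value = 1, n_groups = length(groups), n = nrow(rows),
        skipped = FALSE
      ))
    }
    kt <- kruskal.test(rows$value, factor(rows$group))
    tibble::tibble(
      test_id = id, statistic = unname(kt$statistic),
      df = unname(kt$parameter), p_value = kt$p.value,
      n_groups = length(groups), n = nrow(rows), skipped = FALSE
    )
  })
  out$p_adjusted <- NA_real_
  out$p_adjusted[!out$skipped] <- p.adjust(out$p_value[!out$skipped],
                                           method = "BH")
  out
}

#' Resilience decomposition for literature presence/absence datasets
#'
#' Runs the same resistance / return-rate / recovery-time pipeline on
#' published datasets that provide only species lists per sample: metrics
#' are restricted to species richness (Hill number of order 0) and Jaccard
#' similarity to the reference. Each study must supply reference
#' (undisturbed) samples, disturbed samples and at least one aged secondary
#' sample; studies missing a stage are skipped with a recorded reason, as
#' are similarity analyses for studies with a single reference sample.
#'
#' @param studies A named list; each element is a list with `abundance`
#'   (wide species-by-sample tibble; any positive entry is a presence) and
#'   `samples` (tibble `sample_id`, `stage` in
#'   `reference`/`disturbed`/`secondary`, `age_years` for secondary
#'   samples).
#' @param metrics Metrics to run (`hill_q0`, `jaccard_sim`).
#' @param cap_years,t_eval,alpha As in [summarize_resilience()].
#' @return A list with `summaries` (tibble of per-study rows, `study`
#'   column added) and `skipped` (tibble `study`, `metric`, `reason`).
#' @export
literature_mode <- function(studies, metrics = c("hill_q0", "jaccard_sim"),
                            cap_years = 300, t_eval = 30, alpha = 0.05) {
  stopifnot(all(metrics %in% c("hill_q0", "jaccard_sim")))
  stage_to_category <- c(
    reference = "old_growth", disturbed = "active_cacao",
    secondary = "secondary_cacao"
  )
  results <- list()
  skipped <- list()
  for (study in names(studies)) {
    s <- studies[[study]]
    missing_stage <- setdiff(c("reference", "disturbed", "secondary"),
                             unique(s$samples$stage))
    if (length(missing_stage) > 0) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        study = study, metric = NA_character_,
        reason = paste0("missing stage(s): ",
                        paste(missing_stage, collapse = ", "))
      )
      next
    }
    plots <- validate_plot_table(tibble::tibble(
      plot_id = s$samples$sample_id,
      category = unname(stage_to_category[s$samples$stage]),
      age_years = dplyr::if_else(
        s$samples$stage == "reference", NA_real_,
        dplyr::if_else(s$samples$stage == "disturbed", 0,
                       as.numeric(s$samples$age_years))
      )
    ))
    abundance <- as_abundance_table(s$abundance, plots, taxon = study)
    for (metric in metrics) {
      res <- tryCatch(
        summarize_resilience(
          abundance, plots, metric, taxon = study, legacies = "cacao",
          cap_years = cap_years, t_eval = t_eval, alpha = alpha
        ),
        error = function(e) conditionMessage(e)
      )
      if (is.character(res)) {
        skipped[[length(skipped) + 1]] <- tibble::tibble(
          study = study, metric = metric, reason = res
        )
      } else {
        results[[length(results) + 1]] <- dplyr::rename(res, study = "taxon")
      }
    }
  }
  list(
    summaries = dplyr::bind_rows(results),
    skipped = dplyr::bind_rows(skipped)
  )
}
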