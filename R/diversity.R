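#' Total abundance of a plot
#'
#' @param x Non-negative, finite abundance vector (one plot column).
#' @return Sum of the entries.
#' @export
total_abundance <- function(x) {
  check_abundance_vector(x, allow_zero_total = TRUE)
  sum(x)
}

#' Alpha Hill diversity of one plot
#'
#' Effective number of species of order `q`: `q = 0` is species richness,
#' `q = 1` the exponential of the Shannon entropy of relative abundances,
#' and `q = 2` the inverse Simpson concentration. The orders satisfy
#' `D0 >= D1 >= D2` on any community.
#'
#' @param x Abundance vector with at least one positive entry.
#' @param q Diversity order, one of 0, 1, 2.
#' @return Effective number of species (>= 1).
#' @export
hill_alpha <- function(x, q) {
  check_abundance_vector(x)
  stopifnot(length(q) == 1, q %in% c(0, 1, 2))
  p <- x[x > 0] / sum(x)
  if (q == 1) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Compositional overlap of two plots from beta Hill numbers
#'
#' Partitions the diversity of a pair of assemblages (equal plot weights)
#' into alpha and gamma Hill numbers of order `q`, forms the beta component
#' `Dbeta = Dgamma / Dalpha` (which lies in `[1, 2]` for two assemblages),
#' and transforms it to a similarity in `[0, 1]`. The transform reduces to
#' the Sorensen index at `q = 0`, the Horn index at `q = 1` (where it is
#' evaluated as the limit `(ln 2 - Hbeta) / ln 2` with `Hbeta` the Shannon
#' beta entropy) and the Morisita-Horn index at `q = 2`.
#'
#' Alpha is computed from the joint assemblage of the pair: each species'
#' within-plot relative abundance, halved, enters the Hill sum separately
#' per plot; gamma from the pooled relative abundances.
#'
#' @param a,b Abundance vectors over a common species list; each must have
#'   a positive total.
#' @param q Diversity order, one of 0, 1, 2.
#' @return Overlap similarity in `[0, 1]`.
#' @export
hill_beta_similarity <- function(a, b, q) {
  check_abundance_vector(a)
  check_abundance_vector(b)
  stopifnot(length(a) == length(b), length(q) == 1, q %in% c(0, 1, 2))
  pa <- a / sum(a)
  pb <- b / sum(b)
  pg <- (pa + pb) / 2                  # pooled (gamma) relative abundances
  z <- c(pa, pb) / 2                   # joint-assemblage entries for alpha
  z <- z[z > 0]
  pg <- pg[pg > 0]
  if (q == 1) {
    d_gamma <- exp(-sum(pg * log(pg)))
    d_alpha <- exp(-sum(z * log(z))) / 2
    h_beta <- log(d_gamma / d_alpha)
    overlap <- (log(2) - h_beta) / log(2)
  } else {
    d_gamma <- sum(pg^q)^(1 / (1 - q))
    d_alpha <- sum(z^q)^(1 / (1 - q)) / 2
    d_beta <- min(max(d_gamma / d_alpha, 1), 2)
    overlap <- ((1 / d_beta)^(q - 1) - 0.5^(q - 1)) / (1 - 0.5^(q - 1))
  }
  min(max(overlap, 0), 1)
}

#' Bray-Curtis similarity of two plots
#'
#' Abundances are first transformed to within-plot relative abundances
#' (robustness against unequal totals), then the Bray-Curtis dissimilarity
#' is computed with [vegan::vegdist()] and converted to a similarity as
#' `1 - dissimilarity`.
#'
#' @inheritParams hill_beta_similarity
#' @return Similarity in `[0, 1]`.
#' @export
bray_curtis_similarity <- function(a, b) {
  check_abundance_vector(a)
  check_abundance_vector(b)
  stopifnot(length(a) == length(b))
  pa <- a / sum(a)
  pb <- b / sum(b)
  d <- as.numeric(vegan::vegdist(rbind(pa, pb), method = "bray"))
  min(max(1 - d, 0), 1)
}

#' Jaccard similarity of two plots (presence/absence)
#'
#' @param a,b Vectors over a common species list; any positive entry counts
#'   as presence. The union of the two species sets must be non-empty.
#' @return Shared species / species in the union, in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  pa <- a > 0
  pb <- b > 0
  u <- sum(pa | pb)
  if (u == 0) {
    abort("Jaccard similarity undefined: no species present in either plot.",
          class = "regrow_undefined_input")
  }
  sum(pa & pb) / u
}

pairwise_fun <- function(metric, q = NULL) {
  switch(metric,
    bray_curtis_sim = bray_curtis_similarity,
    jaccard_sim = jaccard_similarity,
    hill_beta_sim_q0 = function(a, b) hill_beta_similarity(a, b, 0),
    hill_beta_sim_q1 = function(a, b) hill_beta_similarity(a, b, 1),
    hill_beta_sim_q2 = function(a, b) hill_beta_similarity(a, b, 2),
    abort(paste0("Not a pairwise similarity metric: ", metric),
          class = "regrow_validation_error")
  )
}

#' All pairwise similarities among plots of one abundance table
#'
#' @param abundance Wide abundance tibble (see [read_abundance_matrix()]).
#' @param metric One of `bray_curtis_sim`, `hill_beta_sim_q0`,
#'   `hill_beta_sim_q1`, `hill_beta_sim_q2`, `jaccard_sim`.
#' @return Long tibble `plot_a`, `plot_b`, `metric`, `value` over unordered
#'   pairs.
#' @export
pairwise_similarity <- function(abundance, metric = "bray_curtis_sim") {
  m <- abundance_matrix(abundance)
  f <- pairwise_fun(metric)
  ids <- colnames(m)
  pairs <- utils::combn(seq_along(ids), 2)
  tibble::tibble(
    plot_a = ids[pairs[1, ]],
    plot_b = ids[pairs[2, ]],
    metric = metric,
    value = purrr::map2_dbl(
      pairs[1, ], pairs[2, ], function(i, j) f(m[, i], m[, j])
    )
  )
}

plot_scalar_fun <- function(metric) {
  switch(metric,
    abundance = total_abundance,
    hill_q0 = function(x) hill_alpha(x, 0),
    hill_q1 = function(x) hill_alpha(x, 1),
    hill_q2 = function(x) hill_alpha(x, 2),
    abort(paste0("Not a per-plot scalar metric: ", metric),
          class = "regrow_validation_error")
  )
}

# central value under the reference-construction rule: median by default,
# mean when the old-growth median is 0 (recovery towards 0 is not
# biologically meaningful)
choose_center_rule <- function(og_values) {
  if (length(og_values) == 0) {
    abort("No old-growth values available to build the reference.",
          class = "regrow_validation_error")
  }
  if (median(og_values) == 0) "mean" else "median"
}

center_value <- function(x, rule) {
  if (rule == "mean") mean(x) else median(x)
}

#' Per-plot metric series with reference and active-plot centers
#'
#' Computes one value per plot for the requested ecological attribute and
#' assembles, for each land-use legacy, the recovery series used by the
#' trajectory fit: active plots at `t = 0` together with the secondary
#' plots of that legacy.
#'
#' For the per-plot scalar metrics (`abundance`, `hill_q0`, `hill_q1`,
#' `hill_q2`) the old-growth reference `psi_ref` is the center of the
#' old-growth plot values. For the similarity metrics each plot's value is
#' its mean pairwise similarity to every old-growth plot, and `psi_ref` is
#' the center over old-growth plots of each plot's mean similarity to the
#' remaining old-growth plots, so that full recovery means being as similar
#' to old growth as old-growth plots are to each other. `psi0` is the
#' center of the active plots of the legacy.
#'
#' The center is the median unless the old-growth median is 0, in which
#' case the mean is used for both `psi0` and `psi_ref`.
#'
#' Plots on which the metric is undefined (zero total abundance) are
#' dropped from the series with a message.
#'
#' @param abundance Wide abundance tibble.
#' @param plots Validated plot table.
#' @param metric One of `abundance`, `hill_q0`, `hill_q1`, `hill_q2`,
#'   `bray_curtis_sim`, `hill_beta_sim_q0`, `hill_beta_sim_q1`,
#'   `hill_beta_sim_q2`, `jaccard_sim`.
#' @param legacies Legacies to assemble series for.
#' @return A tibble `metric`, `legacy`, `plot_id`, `age_years`, `value` with
#'   attributes `centers` (tibble `legacy`, `psi0`, `psi_ref`,
#'   `center_rule`, `n_active`, `n_og`), `og_values` (tibble `plot_id`,
#'   `value` over old-growth plots) and `dropped_plots`.
#' @export
metric_series <- function(abundance, plots, metric,
                          legacies = LEGACIES) {
  if (!metric %in% METRIC_NAMES) {
    abort(paste0("Unknown metric: ", metric), class = "regrow_validation_error")
  }
  m <- abundance_matrix(abundance)
  plots <- dplyr::filter(plots, .data$plot_id %in% colnames(m))
  dropped <- character()

  if (metric %in% SIMILARITY_METRICS) {
    og_ids <- plots$plot_id[plots$category == "old_growth"]
    if (length(og_ids) < 2) {
      abort("At least 2 old-growth plots are required for similarity metrics.",
            class = "regrow_validation_error")
    }
    f <- pairwise_fun(metric)
    usable <- colnames(m)[colSums(m) > 0]
    dropped <- setdiff(colnames(m), usable)
    if (length(dropped) > 0) {
      inform(paste0("Dropping plot(s) with zero total abundance: ",
                    paste(dropped, collapse = ", ")))
    }
    og_ids <- intersect(og_ids, usable)
    if (length(og_ids) < 2) {
      abort("Fewer than 2 usable old-growth plots for similarity metrics.",
            class = "regrow_validation_error")
    }
    mean_sim_to <- function(id, targets) {
      mean(purrr::map_dbl(targets, function(og) f(m[, id], m[, og])))
    }
    non_og <- setdiff(usable, og_ids)
    values <- setNames(
      purrr::map_dbl(non_og, mean_sim_to, targets = og_ids), non_og
    )
    og_values <- setNames(
      purrr::map_dbl(og_ids, function(id) mean_sim_to(id, setdiff(og_ids, id))),
      og_ids
    )
  } else {
    f <- plot_scalar_fun(metric)
    usable <- colnames(m)
    if (metric != "abundance") {
      usable <- colnames(m)[colSums(m) > 0]
      dropped <- setdiff(colnames(m), usable)
      if (length(dropped) > 0) {
        inform(paste0("Dropping plot(s) with zero total abundance: ",
                      paste(dropped, collapse = ", ")))
      }
    }
    all_values <- setNames(
      purrr::map_dbl(usable, function(id) f(m[, id])), usable
    )
    og_ids <- intersect(plots$plot_id[plots$category == "old_growth"], usable)
    og_values <- all_values[og_ids]
    values <- all_values[setdiff(usable, og_ids)]
  }

  rule <- choose_center_rule(unname(og_values))
  psi_ref <- center_value(unname(og_values), rule)

  centers <- purrr::map_dfr(legacies, function(leg) {
    active_ids <- plots$plot_id[
      plots$legacy == leg & plots$age_years %in% 0
    ]
    active_ids <- intersect(active_ids, names(values))
    psi0 <- if (length(active_ids) > 0) {
      center_value(unname(values[active_ids]), rule)
    } else {
      NA_real_
    }
    tibble::tibble(
      legacy = leg, psi0 = psi0, psi_ref = psi_ref, center_rule = rule,
      n_active = length(active_ids), n_og = length(og_values)
    )
  })

  series <- purrr::map_dfr(legacies, function(leg) {
    leg_plots <- dplyr::filter(
      plots, .data$legacy == leg, .data$plot_id %in% names(values)
    )
    tibble::tibble(
      metric = metric,
      legacy = leg,
      plot_id = leg_plots$plot_id,
      age_years = leg_plots$age_years,
      value = unname(values[leg_plots$plot_id])
    )
  })
  structure(
    series,
    centers = centers,
    og_values = tibble::tibble(
      plot_id = names(og_values), value = unname(og_values)
    ),
    dropped_plots = dropped,
    class = class(series)
  )
}

#' Centers attached to a metric series
#'
#' @param series A tibble returned by [metric_series()].
#' @return The `centers` attribute: one row per legacy with `psi0`,
#'   `psi_ref` and the center rule used.
#' @export
series_centers <- function(series) {
  attr(series, "centers", exact = TRUE)
}

check_abundance_vector <- function(x, allow_zero_total = FALSE) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x < 0)) {
    abort("Abundance vector must be non-empty, finite and non-negative.",
          class = "regrow_undefined_input")
  }
  if (!allow_zero_total && sum(x) == 0) {
    abort("Abundance vector has zero total; metric undefined.",
          class = "regrow_undefined_input")
  }
  invisible(x)
}
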