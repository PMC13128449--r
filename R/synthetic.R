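#' Configuration for the synthetic chronosequence generator
#'
#' Bundles and validates the generator parameters. Defaults mirror the
#' chronosequence design the package targets: 6 active plots per legacy,
#' 17/16 secondary plots recovering from cacao/pasture aged 1-38 years, and
#' 17 old-growth reference plots.
#'
#' @param n_active Active plots per legacy.
#' @param n_secondary Named vector `c(cacao = , pasture = )` of secondary
#'   plot counts.
#' @param n_old_growth Old-growth reference plots.
#' @param age_range Integer age range (years since abandonment) for
#'   secondary plots; ages are drawn uniformly on this integer grid.
#' @param lambda_true Generating return rate per year.
#' @param resistance_true Target expected Bray-Curtis similarity of the
#'   disturbed community to the old-growth composition, in `[0, 1]`.
#' @param s_species Species in the old-growth pool.
#' @param n_disturbance_species Disturbance-specialist species (disjoint
#'   from the old-growth pool); must be positive whenever
#'   `resistance_true < 1`.
#' @param abundance_model `lognormal_rank` (lognormal rank-abundance) or
#'   `uniform`.
#' @param n_individuals Individuals sampled per plot (multinomial depth).
#' @param noise_sd Gaussian noise on direct metric series, as a fraction of
#'   `psi_ref`.
#' @param dirichlet_concentration Concentration of the plot-level Dirichlet
#'   perturbation (larger = less plot heterogeneity).
#' @param seed Integer seed; fixes every random draw.
#' @return A validated list of class `chrono_config`.
#' @export
chrono_config <- function(n_active = 6,
                          n_secondary = c(cacao = 17, pasture = 16),
                          n_old_growth = 17,
                          age_range = c(1, 38),
                          lambda_true = 0.05,
                          resistance_true = 0.4,
                          s_species = 100,
                          n_disturbance_species = 40,
                          abundance_model = c("lognormal_rank", "uniform"),
                          n_individuals = 500,
                          noise_sd = 0.05,
                          dirichlet_concentration = 200,
                          seed = 1) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(
    n_active >= 1, all(n_secondary >= 1), n_old_growth >= 2,
    length(age_range) == 2, age_range[1] > 0, age_range[2] <= 60,
    age_range[1] <= age_range[2],
    lambda_true >= 0, resistance_true >= 0, resistance_true <= 1,
    s_species >= 2, n_individuals >= 1, noise_sd >= 0,
    dirichlet_concentration > 0
  )
  if (!all(c("cacao", "pasture") %in% names(n_secondary))) {
    names(n_secondary) <- c("cacao", "pasture")[seq_along(n_secondary)]
  }
  if (resistance_true < 1 && n_disturbance_species < 1) {
    abort(paste0(
      "resistance_true < 1 requires disturbance-specialist species: the ",
      "disturbed community is a mixture of the surviving old-growth ",
      "composition (weight resistance_true) and a disjoint specialist pool."
    ), class = "regrow_config_error")
  }
  structure(
    list(
      n_active = n_active, n_secondary = n_secondary,
      n_old_growth = n_old_growth, age_range = age_range,
      lambda_true = lambda_true, resistance_true = resistance_true,
      s_species = s_species, n_disturbance_species = n_disturbance_species,
      abundance_model = abundance_model, n_individuals = n_individuals,
      noise_sd = noise_sd,
      dirichlet_concentration = dirichlet_concentration,
      seed = seed
    ),
    class = "chrono_config"
  )
}

draw_composition <- function(s, model) {
  x <- switch(model,
    lognormal_rank = sort(rlnorm(s, meanlog = 0, sdlog = 1), decreasing = TRUE),
    uniform = rep(1, s)
  )
  x / sum(x)
}

generator_ages <- function(config) {
  purrr::map(config$n_secondary, function(n) {
    sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  })
}

#' Simulate a direct metric series from the recovery trajectory
#'
#' Evaluates the negative-exponential trajectory (with `psi_ref = 1` and
#' `psi0 = resistance_true`) at the sampled plot ages and adds Gaussian
#' noise with standard deviation `noise_sd * psi_ref`. Active plots sit at
#' `t = 0`. Useful for testing the fitting layer against an exactly known
#' curve, bypassing community sampling.
#'
#' @param config A [chrono_config()].
#' @return A series tibble shaped like [metric_series()] output (metric
#'   `"synthetic"`), with a `centers` attribute holding the generating
#'   `psi0`/`psi_ref` and a `truth` attribute with the generating
#'   parameters.
#' @export
generate_metric_series <- function(config) {
  stopifnot(inherits(config, "chrono_config"))
  set.seed(config$seed)
  psi_ref <- 1
  psi0 <- config$resistance_true
  ages <- generator_ages(config)
  series <- purrr::map_dfr(names(ages), function(leg) {
    t <- c(rep(0, config$n_active), ages[[leg]])
    mu <- recovery_curve(t, config$lambda_true, psi0, psi_ref)
    tibble::tibble(
      metric = "synthetic",
      legacy = leg,
      plot_id = paste0(substr(leg, 1, 1), seq_along(t)),
      age_years = t,
      value = mu + rnorm(length(t), sd = config$noise_sd * psi_ref)
    )
  })
  centers <- tibble::tibble(
    legacy = names(ages), psi0 = psi0, psi_ref = psi_ref,
    center_rule = "median",
    n_active = config$n_active, n_og = config$n_old_growth
  )
  structure(series, centers = centers,
            truth = config, class = class(series))
}

# Monte-Carlo estimate of the map from mixture weight w to the expected
# measured Bray-Curtis similarity of a sampled plot to a sampled old-growth
# plot. Plot-level Dirichlet noise and finite multinomial depth make this
# map nonlinear in w; sampling counts with raw weights w = 1 - exp(-lambda t)
# would therefore bend the expected similarity trajectory away from the
# negative exponential. The generator inverts this map so the expected
# similarity follows the trajectory at exactly the configured rate.
calibrate_mixture_weights <- function(p_dist, p_og, config,
                                      grid = seq(0, 1, by = 0.05),
                                      n_rep = 40) {
  s_w <- purrr::map_dbl(grid, function(w) {
    p_mix <- (1 - w) * p_dist + w * p_og
    mean(purrr::map_dbl(seq_len(n_rep), function(i) {
      x <- sample_plot_counts(p_mix, config)
      y <- sample_plot_counts(p_og, config)
      bray_curtis_similarity(x, y)
    }))
  })
  s_w <- cummax(s_w)  # enforce monotonicity against Monte-Carlo jitter
  s0 <- s_w[1]
  s1 <- s_w[length(s_w)]
  if (s1 - s0 < 1e-6) {
    return(function(t) 1 - exp(-config$lambda_true * t))
  }
  inv <- stats::approxfun(s_w, grid, ties = "ordered", rule = 2)
  function(t) {
    target <- s0 + (s1 - s0) * (1 - exp(-config$lambda_true * t))
    inv(target)
  }
}

# one plot's counts: Dirichlet-perturbed expected composition, then
# multinomial sampling at the configured depth
sample_plot_counts <- function(p_expected, config) {
  shape <- config$dirichlet_concentration * p_expected
  g <- rgamma(length(shape), shape = shape, rate = 1)
  if (sum(g) == 0) g[which.max(p_expected)] <- 1
  as.integer(rmultinom(1, size = config$n_individuals, prob = g / sum(g)))
}

#' Simulate a full community chronosequence with known ground truth
#'
#' Draws an old-growth expected composition from the configured
#' rank-abundance model and builds a disturbed (active-agriculture)
#' composition as a mixture of the surviving old-growth composition
#' (weight `resistance_true`) and a disjoint disturbance-specialist pool
#' (weight `1 - resistance_true`), so the expected Bray-Curtis similarity
#' of the disturbed to the old-growth composition equals
#' `resistance_true`. A plot of age `t` samples its counts from a
#' Dirichlet-perturbed mixture `(1 - w) * p_disturbed + w * p_oldgrowth`
#' with `w = 1 - exp(-lambda_true * t)`, so the expected similarity to the
#' reference follows the negative-exponential trajectory; old-growth plots
#' sample around `p_oldgrowth` itself.
#'
#' Because plot-level Dirichlet heterogeneity and finite sampling depth
#' attenuate measured similarities nonlinearly, the mixing weight is
#' calibrated through a Monte-Carlo estimate of the weight-to-expected-
#' similarity map, so that the expected measured similarity itself follows
#' the negative-exponential trajectory at rate `lambda_true`.
#'
#' @param config A [chrono_config()].
#' @param plots Optional pre-built plot table (used to share one design
#'   across taxa); default generates one from the config.
#' @param taxon Taxon label for the abundance table.
#' @return A list with `plots` (validated plot table), `abundance` (wide
#'   abundance tibble) and `truth` (generating parameters and expected
#'   compositions).
#' @export
generate_community_chronosequence <- function(config, plots = NULL,
                                              taxon = "synthetic_taxon") {
  stopifnot(inherits(config, "chrono_config"))
  set.seed(config$seed)
  if (is.null(plots)) {
    plots <- generate_plot_design(config)
  }
  s_og <- config$s_species
  s_d <- config$n_disturbance_species
  p_og <- c(draw_composition(s_og, config$abundance_model), rep(0, s_d))
  r <- config$resistance_true
  p_dist <- if (r >= 1) {
    p_og
  } else {
    p_spec <- draw_composition(s_d, config$abundance_model)
    c(r * p_og[seq_len(s_og)], (1 - r) * p_spec)
  }
  species <- c(sprintf("og_sp%03d", seq_len(s_og)),
               if (s_d > 0) sprintf("dist_sp%03d", seq_len(s_d)))

  w_at <- calibrate_mixture_weights(p_dist, p_og, config)
  counts <- purrr::map(seq_len(nrow(plots)), function(i) {
    cat_i <- plots$category[i]
    if (cat_i == "old_growth") {
      p_exp <- p_og
    } else {
      w <- w_at(plots$age_years[i])
      p_exp <- (1 - w) * p_dist + w * p_og
    }
    sample_plot_counts(p_exp, config)
  })
  mat <- do.call(cbind, counts)
  colnames(mat) <- plots$plot_id
  abundance <- tibble::as_tibble(
    cbind(tibble::tibble(species_id = species), tibble::as_tibble(mat))
  )
  abundance <- as_abundance_table(abundance, plots, taxon = taxon)
  list(
    plots = plots,
    abundance = abundance,
    truth = list(
      lambda_true = config$lambda_true,
      resistance_true = config$resistance_true,
      p_old_growth = setNames(p_og, species),
      p_disturbed = setNames(p_dist, species),
      config = config
    )
  )
}

generate_plot_design <- function(config) {
  ages <- generator_ages(config)
  plots <- tibble::tibble(
    plot_id = c(
      sprintf("AC%02d", seq_len(config$n_active)),
      sprintf("AP%02d", seq_len(config$n_active)),
      sprintf("SC%02d", seq_along(ages$cacao)),
      sprintf("SP%02d", seq_along(ages$pasture)),
      sprintf("OG%02d", seq_len(config$n_old_growth))
    ),
    category = c(
      rep("active_cacao", config$n_active),
      rep("active_pasture", config$n_active),
      rep("secondary_cacao", length(ages$cacao)),
      rep("secondary_pasture", length(ages$pasture)),
      rep("old_growth", config$n_old_growth)
    ),
    age_years = c(
      rep(0, 2 * config$n_active),
      ages$cacao, ages$pasture,
      rep(NA_real_, config$n_old_growth)
    )
  )
  validate_plot_table(plots)
}

#' A deterministic multi-taxon dataset shaped like a field campaign
#'
#' Builds one 62-plot design (6 + 6 active, 17 + 16 secondary aged 1-38
#' years, 17 old growth) shared by several simulated taxa with contrasting
#' ground-truth recovery dynamics: a fast herbivore (high return rate, high
#' resistance), a mid-speed canopy taxon, a slow detritivore, and an
#' arrested soil community (zero return rate, moderate resistance). A
#' taxon-attribute table (life-history rank, dispersal mode, trophic
#' level) accompanies the communities for grouped comparative tests.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of it.
#' @return A list with `plots`, `abundances` (named list of wide abundance
#'   tibbles), `truth` (tibble of generating parameters per taxon) and
#'   `attributes` (taxon-attribute tibble).
#' @export
generate_study_shaped_dataset <- function(seed = 1) {
  taxa <- tibble::tibble(
    taxon = c("fast_herbivore", "canopy_taxon", "slow_detritivore",
              "arrested_soil"),
    lambda_true = c(0.15, 0.05, 0.01, 0),
    resistance_true = c(0.6, 0.4, 0.2, 0.5),
    life_history_rank = c(2L, 4L, 2L, 1L),
    dispersal = c("aerial", "aerial", "terrestrial", "terrestrial"),
    trophic = c(2L, 1L, 0L, 0L)
  )
  base <- chrono_config(seed = seed)
  set.seed(seed)
  plots <- generate_plot_design(base)
  abundances <- purrr::map(seq_len(nrow(taxa)), function(i) {
    cfg <- chrono_config(
      lambda_true = taxa$lambda_true[i],
      resistance_true = taxa$resistance_true[i],
      seed = seed + i
    )
    generate_community_chronosequence(cfg, plots = plots,
                                      taxon = taxa$taxon[i])$abundance
  })
  names(abundances) <- taxa$taxon
  list(
    plots = plots,
    abundances = abundances,
    truth = taxa[, c("taxon", "lambda_true", "resistance_true")],
    attributes = taxa[, c("taxon", "life_history_rank", "dispersal", "trophic")]
  )
}

#' Write a generated dataset to delimited files
#'
#' Emits exactly the TSV dialect the readers consume, plus a YAML-like
#' manifest of the generating parameters.
#'
#' @param dataset Output of [generate_study_shaped_dataset()] or
#'   [generate_community_chronosequence()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chronosequence <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(dataset$plots, file.path(dir, "plots.tsv"))
  abunds <- dataset$abundances %||% list(taxon = dataset$abundance)
  purrr::iwalk(abunds, function(tbl, nm) {
    readr::write_tsv(tbl, file.path(dir, paste0("abundance_", nm, ".tsv")))
  })
  if (!is.null(dataset$truth) && is.data.frame(dataset$truth)) {
    readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}
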