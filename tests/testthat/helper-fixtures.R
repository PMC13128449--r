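# fixtures are built in code; nothing on disk

# a minimal plot table: n_active per legacy at t = 0, secondary plots at the
# given ages, n_og old-growth plots
make_plots <- function(ages_cacao = c(5, 15, 30), ages_pasture = c(5, 15, 30),
                       n_active = 2, n_og = 3) {
  validate_plot_table(tibble::tibble(
    plot_id = c(
      paste0("AC", seq_len(n_active)), paste0("AP", seq_len(n_active)),
      paste0("SC", seq_along(ages_cacao)), paste0("SP", seq_along(ages_pasture)),
      paste0("OG", seq_len(n_og))
    ),
    category = c(
      rep("active_cacao", n_active), rep("active_pasture", n_active),
      rep("secondary_cacao", length(ages_cacao)),
      rep("secondary_pasture", length(ages_pasture)),
      rep("old_growth", n_og)
    ),
    age_years = c(rep(0, 2 * n_active), ages_cacao, ages_pasture,
                  rep(NA_real_, n_og))
  ))
}

# wide abundance tibble from a species x plot matrix
make_abundance <- function(m, plots, taxon = "toy") {
  tbl <- tibble::as_tibble(m, .name_repair = "minimal")
  names(tbl) <- plots$plot_id[seq_len(ncol(m))]
  tbl <- dplyr::bind_cols(
    tibble::tibble(species_id = paste0("sp", seq_len(nrow(m)))), tbl
  )
  as_abundance_table(tbl, plots, taxon = taxon)
}

# a metric-series tibble with its centers attribute, for driving the fitting
# layer directly
make_series <- function(t, v, psi0, psi_ref, legacy = "cacao",
                        metric = "synthetic", center_rule = "median") {
  series <- tibble::tibble(
    metric = metric, legacy = legacy,
    plot_id = paste0("P", seq_along(t)), age_years = t, value = v
  )
  centers <- tibble::tibble(
    legacy = legacy, psi0 = psi0, psi_ref = psi_ref,
    center_rule = center_rule, n_active = sum(t == 0), n_og = 3L
  )
  structure(series, centers = centers, class = class(series))
}

# independent classical-similarity oracles (textbook formulas, presence or
# relative-abundance based; no shared code with hill_beta_similarity)
oracle_sorensen <- function(a, b) {
  pa <- a > 0
  pb <- b > 0
  2 * sum(pa & pb) / (2 * sum(pa & pb) + sum(pa & !pb) + sum(!pa & pb))
}

oracle_horn <- function(a, b) {
  x <- a / sum(a)
  y <- b / sum(b)
  s <- x + y
  h <- function(z) sum(z[z > 0] * log(z[z > 0]))
  (h(s) - h(x) - h(y)) / (2 * log(2))
}

oracle_morisita_horn <- function(a, b) {
  x <- a / sum(a)
  y <- b / sum(b)
  2 * sum(x * y) / (sum(x^2) + sum(y^2))
}

# dense grid-search least-squares oracle for the single-parameter fit
oracle_grid_lambda <- function(t, v, psi0, psi_ref,
                               grid = seq(0, 1, by = 1e-4)) {
  sse <- vapply(
    grid,
    function(l) sum((v - (psi0 + (psi_ref - psi0) * (1 - exp(-l * t))))^2),
    numeric(1)
  )
  grid[which.min(sse)]
}

random_community_pair <- function(n_species = 8, zero_prob = 0.3) {
  repeat {
    a <- rpois(n_species, 5) * rbinom(n_species, 1, 1 - zero_prob)
    b <- rpois(n_species, 5) * rbinom(n_species, 1, 1 - zero_prob)
    if (sum(a) > 0 && sum(b) > 0) return(list(a = as.numeric(a), b = as.numeric(b)))
  }
}
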