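test_that("a constant predictor carries no impurity importance", {
  set.seed(2)
  rate <- runif(30, 0.01, 0.3)
  rows <- tibble::tibble(
    resistance_pct = 40,
    return_rate = rate,
    recovery_time_years = -log(0.1 / 0.6) / rate
  )
  imp <- importance_rf(rows, seed = 5)
  expect_equal(imp$importance[imp$predictor == "resistance"], 0,
               tolerance = 1e-9)
  expect_gt(imp$importance[imp$predictor == "return_rate"], 0)
})

test_that("rate-driven recovery times rank the rate above resistance", {
  set.seed(3)
  n <- 40
  resist <- runif(n, 30, 50)              # narrow band: weak signal
  rate <- runif(n, 0.01, 0.3)             # dominant driver
  rows <- tibble::tibble(
    resistance_pct = resist,
    return_rate = rate,
    recovery_time_years = vapply(seq_len(n), function(i) {
      recovery_time(resist[i], rate[i], resist[i] / 100, 1)
    }, numeric(1))
  )
  imp <- importance_rf(rows, seed = 7)
  expect_gt(imp$ratio_return_to_resistance[1], 1)
})

test_that("instant and undefined rows are excluded and the forest is seeded", {
  set.seed(4)
  rows <- tibble::tibble(
    resistance_pct = c(runif(8, 10, 80), 95, 97),
    return_rate = c(runif(8, 0.01, 0.3), NA, NA),
    recovery_time_years = c(runif(7, 5, 200), Inf, 0, 0)
  )
  imp <- importance_rf(rows, seed = 11)
  expect_equal(imp$excluded_instant[1], 2)
  expect_equal(imp$excluded_undefined[1], 1)
  expect_equal(imp$n_taxa[1], 7)
  imp2 <- importance_rf(rows, seed = 11)
  expect_identical(imp$importance, imp2$importance)
  skipped <- importance_rf(rows[1:4, ], seed = 11)
  expect_true(all(skipped$skipped))
})

test_that("forest importances ignore taxon row order", {
  set.seed(6)
  rows <- tibble::tibble(
    resistance_pct = runif(20, 5, 85),
    return_rate = runif(20, 0.01, 0.3)
  )
  rows$recovery_time_years <- vapply(seq_len(20), function(i) {
    recovery_time(rows$resistance_pct[i], rows$return_rate[i],
                  rows$resistance_pct[i] / 100, 1)
  }, numeric(1))
  shuffled <- rows[sample(nrow(rows)), ]
  ordered1 <- dplyr::arrange(rows, resistance_pct)
  ordered2 <- dplyr::arrange(shuffled, resistance_pct)
  expect_identical(importance_rf(ordered1, seed = 3)$importance,
                   importance_rf(ordered2, seed = 3)$importance)
})

test_that("Spearman correlation handles monotone, reversed and printed inputs", {
  mono <- tibble::tibble(resistance_pct = 1:6, return_rate = (1:6)^2 / 100)
  expect_equal(spearman_resistance_vs_return(mono)$rho, 1)
  rev <- tibble::tibble(resistance_pct = 1:6, return_rate = rev(1:6) / 100)
  expect_equal(spearman_resistance_vs_return(rev)$rho, -1)

  # published per-taxon composition columns under cacao legacy (rounded);
  # the unrounded original reports -0.41, midranks on the rounded values
  # land close by
  printed <- tibble::tibble(
    resistance_pct = c(88, 67, 46, 81, 22, 24, 56, 42, 34, 44, 0, 54, 0, 72,
                       30, 0, 1),
    return_rate = c(0, 0, 2, 0, 178, 16, 28, 97, 53, 34, 27, 85, 165, 165,
                    40, 40, 25) * 1e-3
  )
  out <- spearman_resistance_vs_return(printed)
  expect_equal(out$n, 17)
  expect_true(out$rho <= -0.38 && out$rho >= -0.41)
  expect_gt(out$p_value, 0.05)  # not significant, as reported
})

test_that("monotone transforms of either variable leave Spearman unchanged", {
  set.seed(8)
  rows <- tibble::tibble(resistance_pct = runif(12, 1, 99),
                         return_rate = runif(12, 0.001, 0.3))
  base <- spearman_resistance_vs_return(rows)$rho
  transformed <- tibble::tibble(
    resistance_pct = log(rows$resistance_pct),
    return_rate = rows$return_rate^3
  )
  expect_equal(spearman_resistance_vs_return(transformed)$rho, base)
})

test_that("the signed-rank test drops zeros and respects its symmetry", {
  same <- wilcoxon_paired(c(1, 2, 3), c(1, 2, 3))
  expect_false(same$defined)
  expect_equal(same$n_dropped, 3)

  out <- wilcoxon_paired(c(1, 2, 3), c(2, 4, 6))
  expect_equal(out$V, 0)
  expect_equal(out$n_pairs, 3)

  a <- c(5, 9, 2, 7, 1)
  b <- c(3, 4, 8, 2, 6)
  v_ab <- wilcoxon_paired(a, b)$V
  v_ba <- wilcoxon_paired(b, a)$V
  n <- 5
  expect_equal(v_ab + v_ba, n * (n + 1) / 2)
})

test_that("Kruskal-Wallis tests run per family with BH adjustment", {
  flat <- tibble::tibble(
    test_id = "t", value = rep(2, 6), group = rep(c("a", "b"), 3)
  )
  expect_equal(kruskal_fdr(flat)$statistic, 0)

  two <- tibble::tibble(
    test_id = "t", value = c(1, 2, 3, 10, 11, 12),
    group = rep(c("a", "b"), each = 3)
  )
  expect_equal(kruskal_fdr(two)$statistic, 3.857, tolerance = 1e-3)

  fam <- dplyr::bind_rows(
    dplyr::mutate(two, test_id = "u"),
    dplyr::mutate(two, test_id = "v"),
    dplyr::mutate(two, test_id = "w")
  )
  out <- kruskal_fdr(fam)
  expect_equal(out$p_adjusted, out$p_value)  # identical p's are a BH fixed point

  one_group <- tibble::tibble(test_id = "s", value = 1:3, group = "a")
  expect_true(kruskal_fdr(one_group)$skipped)
})

test_that("BH adjustment preserves the ordering of raw p-values", {
  set.seed(10)
  fam <- purrr::map_dfr(1:6, function(i) tibble::tibble(
    test_id = paste0("t", i),
    value = rnorm(12, mean = i %% 3),
    group = rep(c("a", "b"), 6)
  ))
  out <- kruskal_fdr(fam)
  # monotone: adjusted values never cross when raw p-values are ordered
  # (ties in the adjusted values are expected from the step-up construction)
  expect_true(all(diff(out$p_adjusted[order(out$p_value)]) >= -1e-15))
  expect_true(all(out$p_adjusted >= out$p_value))
})

test_that("literature mode recovers ground truth from presence data", {
  cfg <- chrono_config(lambda_true = 0.08, resistance_true = 0.3,
                       n_active = 4,
                       n_secondary = c(cacao = 10, pasture = 1),
                       n_old_growth = 6, s_species = 60,
                       n_disturbance_species = 30, seed = 14)
  d <- generate_community_chronosequence(cfg)
  keep <- d$plots$category %in% c("active_cacao", "secondary_cacao", "old_growth")
  samples <- tibble::tibble(
    sample_id = d$plots$plot_id[keep],
    stage = dplyr::case_match(
      d$plots$category[keep],
      "active_cacao" ~ "disturbed",
      "secondary_cacao" ~ "secondary",
      "old_growth" ~ "reference"
    ),
    age_years = d$plots$age_years[keep]
  )
  presence <- d$abundance
  presence[, -1] <- lapply(presence[, -1], function(x) as.numeric(x > 0))
  presence <- presence[, c(TRUE, keep)]
  out <- suppressMessages(literature_mode(
    list(study_a = list(abundance = presence, samples = samples))
  ))
  expect_setequal(out$summaries$metric, c("hill_q0", "jaccard_sim"))
  jac <- out$summaries[out$summaries$metric == "jaccard_sim", ]
  expect_lt(abs(jac$return_rate - 0.08) / 0.08, 0.6)
})

test_that("literature mode skips studies missing a stage or a usable reference", {
  plots <- make_plots(n_og = 3)
  ab <- make_abundance(matrix(1, 3, nrow(plots)), plots)
  no_secondary <- list(
    abundance = ab[, c("species_id", "AC1", "AC2", "OG1", "OG2", "OG3")],
    samples = tibble::tibble(
      sample_id = c("AC1", "AC2", "OG1", "OG2", "OG3"),
      stage = c("disturbed", "disturbed", rep("reference", 3)),
      age_years = NA_real_
    )
  )
  single_reference <- list(
    abundance = ab[, c("species_id", "AC1", "SC1", "OG1")],
    samples = tibble::tibble(
      sample_id = c("AC1", "SC1", "OG1"),
      stage = c("disturbed", "secondary", "reference"),
      age_years = c(NA, 10, NA)
    )
  )
  out <- suppressMessages(literature_mode(
    list(a = no_secondary, b = single_reference)
  ))
  expect_equal(nrow(out$skipped[out$skipped$study == "a", ]), 1)
  jac_skip <- out$skipped[out$skipped$study == "b" &
                            out$skipped$metric == "jaccard_sim", ]
  expect_equal(nrow(jac_skip), 1)
})

test_that("a secondary community identical to the reference classifies instant", {
  plots <- make_plots(ages_cacao = c(10, 20, 30), n_active = 2, n_og = 3)
  m <- matrix(rep(c(4, 6, 2), nrow(plots)), nrow = 3)
  ab <- make_abundance(m, plots)
  samples <- tibble::tibble(
    sample_id = plots$plot_id,
    stage = dplyr::case_match(
      plots$category,
      c("active_cacao", "active_pasture") ~ "disturbed",
      c("secondary_cacao", "secondary_pasture") ~ "secondary",
      "old_growth" ~ "reference"
    ),
    age_years = plots$age_years
  )
  out <- suppressMessages(literature_mode(
    list(s = list(abundance = ab, samples = samples))
  ))
  expect_true(all(out$summaries$classification == "instant"))
})
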