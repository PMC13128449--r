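test_that("total abundance sums plot columns", {
  expect_equal(total_abundance(c(3, 0, 7)), 10)
  expect_equal(total_abundance(rep(0, 4)), 0)
  expect_equal(total_abundance(c(1.5, 2.5)), 4.0)
  expect_error(total_abundance(c(1, -1)), class = "regrow_undefined_input")
})

test_that("alpha Hill numbers match their closed forms", {
  for (q in 0:2) expect_equal(hill_alpha(c(5, 5, 5, 5), q), 4)
  expect_equal(hill_alpha(c(75, 25), 0), 2)
  expect_equal(hill_alpha(c(75, 25), 1),
               exp(-(0.75 * log(0.75) + 0.25 * log(0.25))))
  expect_equal(hill_alpha(c(75, 25), 2), 1 / (0.75^2 + 0.25^2))
  for (q in 0:2) expect_equal(hill_alpha(c(0, 9, 0), q), 1)
  expect_error(hill_alpha(c(0, 0), 1), class = "regrow_undefined_input")
})

test_that("Hill diversity is non-increasing in the order q", {
  set.seed(42)
  for (i in 1:50) {
    x <- rpois(sample(2:20, 1), lambda = sample(1:10, 1)) + 0
    if (sum(x) == 0) x[1] <- 1
    d <- vapply(0:2, function(q) hill_alpha(x, q), numeric(1))
    expect_true(d[1] >= d[2] - 1e-12 && d[2] >= d[3] - 1e-12)
  }
})

test_that("beta-Hill overlap hits its endpoint and worked cases", {
  for (q in 0:2) {
    expect_equal(hill_beta_similarity(c(3, 1, 2), c(3, 1, 2), q), 1)
    expect_equal(hill_beta_similarity(c(6, 2, 4), c(3, 1, 2), q), 1)
  }
  expect_equal(hill_beta_similarity(c(5, 5, 0, 0), c(0, 0, 5, 5), 0), 0)
  expect_equal(hill_beta_similarity(c(10, 10, 0), c(0, 10, 10), 0), 0.5)
  expect_error(hill_beta_similarity(c(0, 0), c(1, 1), 1),
               class = "regrow_undefined_input")
})

test_that("beta-Hill overlap equals the classical indices on random communities", {
  set.seed(7)
  for (i in 1:200) {
    pair <- random_community_pair()
    expect_equal(hill_beta_similarity(pair$a, pair$b, 0),
                 oracle_sorensen(pair$a, pair$b), tolerance = 1e-10)
    expect_equal(hill_beta_similarity(pair$a, pair$b, 1),
                 oracle_horn(pair$a, pair$b), tolerance = 1e-10)
    expect_equal(hill_beta_similarity(pair$a, pair$b, 2),
                 oracle_morisita_horn(pair$a, pair$b), tolerance = 1e-10)
  }
})

test_that("Bray-Curtis similarity works on relative abundances", {
  expect_equal(bray_curtis_similarity(c(2, 2, 0), c(1, 1, 0)), 1)
  expect_equal(bray_curtis_similarity(c(1, 0), c(0, 3)), 0)
  expect_equal(bray_curtis_similarity(c(75, 25, 0), c(0, 25, 75)), 0.25)
  expect_error(bray_curtis_similarity(c(0, 0), c(1, 1)),
               class = "regrow_undefined_input")
})

test_that("Jaccard similarity counts shared species over the union", {
  expect_equal(jaccard_similarity(c(1, 1, 1), c(2, 5, 9)), 1)
  expect_equal(jaccard_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(jaccard_similarity(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_error(jaccard_similarity(c(0, 0), c(0, 0)),
               class = "regrow_undefined_input")
})

test_that("similarities are symmetric, 1 on identical and 0 on disjoint inputs", {
  set.seed(11)
  metrics <- list(
    function(a, b) bray_curtis_similarity(a, b),
    function(a, b) jaccard_similarity(a, b),
    function(a, b) hill_beta_similarity(a, b, 0),
    function(a, b) hill_beta_similarity(a, b, 1),
    function(a, b) hill_beta_similarity(a, b, 2)
  )
  for (i in 1:25) {
    pair <- random_community_pair()
    for (f in metrics) {
      expect_equal(f(pair$a, pair$b), f(pair$b, pair$a), tolerance = 1e-12)
      v <- f(pair$a, pair$b)
      expect_true(v >= 0 && v <= 1)
    }
  }
  disjoint_a <- c(4, 2, 0, 0)
  disjoint_b <- c(0, 0, 4, 2)
  expect_equal(bray_curtis_similarity(disjoint_a, disjoint_b), 0)
  expect_equal(jaccard_similarity(disjoint_a, disjoint_b), 0)
  expect_equal(hill_beta_similarity(disjoint_a, disjoint_b, 0), 0)
})

test_that("abundance-based similarities are invariant to rescaling one plot", {
  set.seed(13)
  for (i in 1:25) {
    pair <- random_community_pair()
    k <- runif(1, 0.1, 40)
    expect_equal(bray_curtis_similarity(pair$a * k, pair$b),
                 bray_curtis_similarity(pair$a, pair$b), tolerance = 1e-12)
    for (q in 0:2) {
      expect_equal(hill_beta_similarity(pair$a * k, pair$b, q),
                   hill_beta_similarity(pair$a, pair$b, q), tolerance = 1e-12)
    }
  }
})

test_that("the old-growth reference is the median of mean within-reference similarity", {
  # two-species compositions placed so the three pairwise Bray-Curtis
  # similarities are 0.8, 0.6 and 0.4; per-plot means (0.7, 0.6, 0.5)
  plots <- make_plots(n_active = 2, n_og = 3)
  m <- matrix(0, nrow = 2, ncol = nrow(plots))
  m[, ] <- c(5, 5)  # every plot starts at (0.5, 0.5)
  og_cols <- which(plots$category == "old_growth")
  m[, og_cols[1]] <- c(5, 5)    # 0.5
  m[, og_cols[2]] <- c(7, 3)    # 0.7
  m[, og_cols[3]] <- c(1, 9)    # 0.1
  ab <- make_abundance(m, plots)
  series <- metric_series(ab, plots, "bray_curtis_sim")
  og_vals <- attr(series, "og_values")
  expect_equal(sort(og_vals$value, decreasing = TRUE), c(0.7, 0.6, 0.5))
  expect_equal(unique(series_centers(series)$psi_ref), 0.6)

  # identical composition everywhere: every similarity and the reference are 1
  m1 <- matrix(rep(c(3, 7), nrow(plots)), nrow = 2)
  ab1 <- make_abundance(m1, plots)
  s1 <- metric_series(ab1, plots, "bray_curtis_sim")
  expect_true(all(s1$value == 1))
  expect_equal(unique(series_centers(s1)$psi_ref), 1)

  # a single old-growth plot cannot define a reference
  plots_one_og <- make_plots(n_og = 1)
  ab_one <- make_abundance(matrix(1, 2, nrow(plots_one_og)), plots_one_og)
  expect_error(metric_series(ab_one, plots_one_og, "bray_curtis_sim"),
               class = "regrow_validation_error")
})

test_that("the center rule switches to the mean only when the old-growth median is 0", {
  plots <- make_plots(n_active = 2, n_og = 3)
  m <- matrix(0, nrow = 1, ncol = nrow(plots))
  m[1, ] <- 1
  og_cols <- which(plots$category == "old_growth")
  m[1, og_cols] <- c(0, 0, 5)
  ab <- make_abundance(m, plots)
  series <- metric_series(ab, plots, "abundance")
  ctr <- series_centers(series)
  expect_equal(unique(ctr$center_rule), "mean")
  expect_equal(unique(ctr$psi_ref), 5 / 3)

  m[1, og_cols] <- c(2, 4, 6)
  ab2 <- make_abundance(m, plots)
  ctr2 <- series_centers(metric_series(ab2, plots, "abundance"))
  expect_equal(unique(ctr2$center_rule), "median")
  expect_equal(unique(ctr2$psi_ref), 4)
})

test_that("a legacy without active plots yields an undefined psi0 and no fit", {
  plots <- make_plots(n_active = 2, n_og = 3)
  plots <- plots[plots$category != "active_pasture", ]
  m <- matrix(rpois(3 * nrow(plots), 5) + 1, nrow = 3)
  ab <- make_abundance(m, plots)
  series <- metric_series(ab, plots, "hill_q1")
  ctr <- series_centers(series)
  expect_true(is.na(ctr$psi0[ctr$legacy == "pasture"]))
  expect_error(fit_recovery(series, legacy = "pasture"),
               class = "regrow_validation_error")
})

test_that("pairwise similarity tables cover all unordered pairs symmetrically", {
  plots <- make_plots()
  set.seed(3)
  ab <- make_abundance(matrix(rpois(4 * nrow(plots), 4) + 1, nrow = 4), plots)
  pw <- pairwise_similarity(ab, "bray_curtis_sim")
  n <- nrow(plots)
  expect_equal(nrow(pw), n * (n - 1) / 2)
  expect_true(all(pw$value >= 0 & pw$value <= 1))
})
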