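test_that("choice simplicity: constant-value and linear closed forms", {
  # symmetric line under EV: every bundle has equal value -> index 0
  expect_equal(choice_simplicity(budget_set(1, 1, 100), ev_params()), 0)
  # EV on the 100/50 line: v(x) = x/4 + 25 linear in x, V = 50 at the X
  # corner; mean gap 12.5; endowment 100/3 -> 0.375 exactly
  expect_equal(choice_simplicity(budget_set(1, 2, 100), ev_params()), 0.375)
  # same value from the closed form (V - mean v) / endowment with any N
  expect_equal(choice_simplicity(budget_set(1, 2, 100), ev_params(),
                                 n_points = 11), 0.375)
  # expenditure normalization option
  expect_equal(choice_simplicity(budget_set(1, 2, 100), ev_params(),
                                 normalize = "expenditure"), 12.5 / 100)
  expect_error(choice_simplicity(budget_set(1, 2, 100), ev_params(),
                                 n_points = 1))
})

test_that("simplicity agrees with a dense independent evaluation", {
  p <- utility_params("DA_CRRA", beta = 1, rho = 1)
  b <- budget_set(1 / 90, 1 / 40, 1)
  got <- choice_simplicity(b, p, n_points = 1000)
  xs <- seq(0, 90, length.out = 1000)
  ys <- pmax((1 - xs / 90) * 40, 0)
  v <- subjective_value(xs, ys, p)
  expect_equal(got, (max(v) - mean(v)) / safe_portfolio(b),
               tolerance = 1e-12)
  expect_gte(got, 0)
})

test_that("simplicity is invariant to rescaling and account swap", {
  p <- utility_params("DA_CRRA", beta = 0.7, rho = 1.3)
  b1 <- budget_set(1, 2, 100)
  b2 <- budget_set(3, 6, 300)       # same line, rescaled
  expect_equal(choice_simplicity(b1, p), choice_simplicity(b2, p))
  b3 <- budget_set(2, 1, 100)       # accounts swapped
  expect_equal(choice_simplicity(b1, p), choice_simplicity(b3, p),
               tolerance = 1e-9)
})

test_that("regressor table columns reproduce hand arithmetic", {
  truth <- utility_params("DA_CRRA", beta = 0.4, rho = 0.9)
  ds <- simulate_subject(12, "maximize", seed = 61, params = truth)
  fit <- aggregate_mmi(ds, grid_n = 9)
  tab <- regressor_table(ds, fit)
  expect_equal(nrow(tab), 12)
  expect_equal(tab$price_ratio, log(ds$price_x / ds$price_y))
  expect_equal(tab$endowment,
               ds$expenditure / (ds$price_x + ds$price_y))
  expect_equal(tab$confidence, tab$sv^2)
  expect_equal(tab$sv,
               subjective_value(ds$x, ds$y, fit$params))
  # consistent maximizer data: trial-specific MMI all ~0
  expect_true(all(abs(tab$trial_mmi) < 1e-6))
  # three hand-computed toy lines
  toy <- choice_dataset(data.frame(price_x = c(1, 1, 2),
                                   price_y = c(2, 4, 1),
                                   expenditure = c(100, 100, 100),
                                   x = c(20, 20, 10),
                                   y = c(40, 20, 80)))
  fit_toy <- list(params = ev_params(), family = "DA_CRRA",
                  aggregator = "rms")
  tab_toy <- regressor_table(toy, fit_toy,
                             loo_series = list(values = c(0, 0, 0)))
  expect_equal(tab_toy$price_ratio, c(log(1 / 2), log(1 / 4), log(2)))
  expect_equal(tab_toy$endowment, c(100 / 3, 20, 100 / 3))
  # SV depends only on the chosen bundle, not on the trial's price scale
  toy2 <- toy
  toy2$price_x <- toy2$price_x * 7
  toy2$price_y <- toy2$price_y * 7
  toy2$expenditure <- toy2$expenditure * 7
  tab_toy2 <- regressor_table(choice_dataset(as.data.frame(toy2)), fit_toy,
                              loo_series = list(values = c(0, 0, 0)))
  expect_equal(tab_toy2$sv, tab_toy$sv)
  expect_error(regressor_table(toy, fit_toy,
                               loo_series = list(values = c(0, 0))),
               "length")
})

test_that("trial-specific MMI relates only weakly to simplicity", {
  # random-utility subjects at a realistic inconsistency level: choice
  # difficulty explains little of the trial-specific MMI variance.  (The
  # sign of the weak association is not stable across simulated subjects
  # at desk scale: flips are more frequent on difficult trials but each
  # flip costs little expenditure adjustment there - see the vignette.)
  truth <- utility_params("DA_CRRA", beta = 0.5, rho = 0.5)
  pool_mmi <- pool_simp <- NULL
  for (rep in 1:3) {
    budgets <- generate_budgets(108, seed = 1000 + rep)
    sim <- nrum_simulate(budgets, truth, noise_spec("gumbel", 0.1),
                         seed = 1000 + rep)
    ds <- sim$dataset
    fit <- aggregate_mmi(ds, grid_n = 11, n_starts = 1, refine_maxit = 50)
    lm <- loo_index(ds, "mmi", mmi_full = fit, loo_grid_n = 5,
                    loo_refine_maxit = 12)
    simp <- vapply(seq_len(nrow(ds)), function(k)
      choice_simplicity(ds[k, ], fit$params, n_points = 200), 0)
    pool_mmi <- c(pool_mmi, lm$values)
    pool_simp <- c(pool_simp, simp)
  }
  r <- cor(pool_mmi, pool_simp)
  expect_lt(r^2, 0.1)
})
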