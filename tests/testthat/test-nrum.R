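test_that("noise families have the advertised location and skew", {
  set.seed(2)
  g <- rpindex:::draw_noise(2e5, noise_spec("gumbel", 0.5))
  ln <- rpindex:::draw_noise(2e5, noise_spec("lognormal", 0.7))
  # lognormal variant is mean-zero by construction
  expect_lt(abs(mean(ln)), 0.01)
  # gumbel mode at 0: histogram peak near 0
  h <- hist(g, breaks = seq(min(g) - 0.1, max(g) + 0.1, by = 0.05),
            plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)]), 0.1)
  # both families are right-skewed at any scale
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew(g), 0.5)
  expect_gt(skew(ln), 0.5)
  expect_error(noise_spec("gumbel", -1))
})

test_that("the noiseless limit reproduces the deterministic optimum", {
  truth <- utility_params("DA_CRRA", beta = 0.8, rho = 0.7)
  budgets <- generate_budgets(15, seed = 3)
  sim <- nrum_simulate(budgets, truth, noise_spec("gumbel", 1e-9), seed = 4)
  for (k in 1:15) {
    ob <- optimal_bundle(budgets[k, ], truth)
    expect_lt(abs(sim$dataset$x[k] - ob$bundle[["x"]]), 0.11)
  }
  expect_equal(garp_violations(sim$dataset)$n_violations, 0L)
  # finite noise generally breaks GARP on the same budgets
  noisy <- nrum_simulate(budgets, truth, noise_spec("gumbel", 0.5), seed = 4)
  big <- nrum_simulate(generate_budgets(108, seed = 3), truth,
                       noise_spec("gumbel", 0.5), seed = 4)
  expect_gt(garp_violations(big$dataset)$n_violations, 0L)
})

test_that("noise calibration hits the target Afriat level", {
  truth <- utility_params("DA_CRRA", beta = 0.5, rho = 0.5)
  budgets <- generate_budgets(108, seed = 5)
  ns <- calibrate_noise(budgets, truth, target_afriat = 0.05,
                        family = "gumbel", reps = 30, seed = 2)
  expect_true(abs(attr(ns, "achieved_afriat") - 0.05) <= 0.005 + 1e-9)
  # round trip on a fresh seed (value grids precomputed once for speed)
  vg <- rpindex:::value_grids(budgets, truth)
  mean_afr <- mean(vapply(1:30, function(r) {
    sim <- nrum_simulate(budgets, truth, ns, seed = 5000 + r, v_grids = vg)
    afriat_index(sim$dataset, method = "exact")
  }, 0))
  expect_equal(mean_afr, 0.05, tolerance = 0.4)
  # mean Afriat is nondecreasing in scale (common random numbers)
  scales <- c(0.05, 0.15, 0.45, 1.2)
  means <- vapply(scales, function(s) {
    mean(vapply(1:20, function(r) {
      sim <- nrum_simulate(budgets, truth, noise_spec("gumbel", s),
                           seed = rpindex:::trial_seed(2, r, 3L),
                           v_grids = vg)
      afriat_index(sim$dataset, method = "exact")
    }, 0))
  }, 0)
  expect_true(all(diff(means) >= -1e-9))
  # target 0 returns the lower search bound
  ns0 <- calibrate_noise(budgets, truth, target_afriat = 0,
                         family = "gumbel", reps = 10, seed = 1)
  expect_lt(ns0$scale, 1e-6)
  expect_error(calibrate_noise(budgets, truth, target_afriat = 0.4,
                               family = "gumbel", reps = 10, seed = 1,
                               scale_bounds = c(1e-8, 1e-6)),
               "unattainable")
})

test_that("pooled noise-inconsistency correlation is positive and robust", {
  truth <- utility_params("DA_CRRA", beta = 0.5, rho = 0.5)
  budgets <- generate_budgets(108, seed = 5)
  run <- nrum_assess(budgets, truth, noise_spec("gumbel", 0.22),
                     n_reps = 150, seed = 7)
  expect_gt(run$pooled_r, 0)
  expect_lt(run$pooled_p, 1e-10)
  expect_true(all(run$trial_afriat >= 0))
  expect_equal(length(run$chosen_noise), length(run$trial_afriat))
  # shuffling the noise across trials destroys the link (permutation null)
  set.seed(1)
  shuffled <- sample(as.vector(run$chosen_noise))
  r_perm <- cor(shuffled, as.vector(run$trial_afriat))
  expect_lt(abs(r_perm), abs(run$pooled_r) / 2)
  # reproducibility of the full pipeline
  run2 <- nrum_assess(budgets, truth, noise_spec("gumbel", 0.22),
                      n_reps = 150, seed = 7)
  expect_identical(run$pooled_r, run2$pooled_r)
})

test_that("two-alternative demo matches the closed-form lognormal oracle", {
  d <- conditional_utility_demo(c(4, 2), log_sd = 0.7, n_samples = 4e5,
                                seed = 9)
  p_closed <- pnorm(-log(2) / (0.7 * sqrt(2)))
  expect_equal(d$choice_prob[2], p_closed, tolerance = 0.01)
  expect_equal(sum(d$choice_prob), 1)
  # the inconsistent option's utility is inflated when it is chosen
  expect_gt(d$mean_chosen_utility[2], d$mean_value[2])
  # gap effect: widening the valuation gap raises the conditional mean
  d_wide <- conditional_utility_demo(c(7, 2), log_sd = 0.7,
                                     n_samples = 4e5, seed = 9)
  expect_gt(d_wide$mean_chosen_utility[2], d$mean_chosen_utility[2])
})

test_that("additive-noise demo shows the severity gradient", {
  d6 <- conditional_utility_demo(7:2, log_sd = 0.7, n_samples = 4e5,
                                 noise_type = "additive", seed = 10)
  cm <- d6$mean_chosen_utility[-1]  # inconsistent alternatives 2..6
  se <- d6$se_chosen_utility[-1]
  # conditional mean utility increases as worse alternatives are chosen
  expect_true(all(diff(cm) > -2 * (se[-1] + se[-length(se)])))
  expect_gt(cm[length(cm)], cm[1])
})
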