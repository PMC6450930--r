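test_that("subjective value reproduces the named special cases", {
  # beta = 0, rho = 0: expected value
  expect_equal(subjective_value(10, 30, ev_params()), 20)
  # beta = -1: only the larger amount matters (elation-seeking limit)
  expect_equal(subjective_value(10, 30,
                                utility_params("DA_CRRA", -1, rho = 0)), 30)
  # hand-computed DA-CRRA value: gamma = 1/4, omega(z) = 2 sqrt(z)
  p <- utility_params("DA_CRRA", beta = 2, rho = 0.5)
  expect_equal(subjective_value(10, 30, p),
               0.25 * 2 * sqrt(30) + 0.75 * 2 * sqrt(10))
  # CARA curvature
  pc <- utility_params("DA_CARA", beta = 0, A = 0.05)
  expect_equal(subjective_value(10, 30, pc),
               0.5 * (1 - exp(-0.5)) + 0.5 * (1 - exp(-1.5)))
  expect_error(utility_params("DA_CRRA", beta = -1.5, rho = 1))
  expect_error(utility_params("DA_CRRA", beta = 0, rho = 1, A = 2))
})

test_that("subjective value is symmetric and reduces to EU at beta = 0", {
  set.seed(11)
  for (i in 1:20) {
    x <- runif(1, 0, 100); y <- runif(1, 0, 100)
    p <- utility_params("DA_CRRA", beta = runif(1, -1, 5),
                        rho = runif(1, 0, 3))
    expect_equal(subjective_value(x, y, p), subjective_value(y, x, p))
  }
  # beta = 0 gives gamma = 1/2: plain expected utility
  p0 <- utility_params("DA_CRRA", beta = 0, rho = 1.4)
  x <- runif(20, 0.5, 90); y <- runif(20, 0.5, 90)
  ww <- function(z) z^(1 - 1.4) / (1 - 1.4)
  expect_equal(subjective_value(x, y, p0), 0.5 * ww(x) + 0.5 * ww(y))
})

test_that("optimal bundles match the closed-form benchmarks", {
  b <- budget_set(1, 2, 100)
  # extreme disappointment aversion: the safe 45-degree bundle
  leontief <- utility_params("DA_CRRA", beta = 1e6, rho = 0.5)
  ob <- optimal_bundle(budget_set(1, 1, 100), leontief)
  expect_equal(unname(ob$bundle), c(50, 50), tolerance = 1e-6)
  ob2 <- optimal_bundle(b, leontief)
  expect_equal(unname(ob2$bundle["x"]), unname(ob2$bundle["y"]),
               tolerance = 1e-6)
  # linear objective (EV): cheaper-good corner
  obc <- optimal_bundle(b, ev_params())
  expect_equal(unname(obc$bundle), c(100, 0))
  # Cobb-Douglas with equal exponents: the half-expenditure split
  cd <- optimal_bundle(b, utility_params("DA_CRRA", beta = 0, rho = 1))
  expect_equal(unname(cd$bundle), c(50, 25), tolerance = 1e-5)
})

test_that("optimal bundle agrees with a dense grid argmax", {
  set.seed(21)
  for (i in 1:12) {
    budgets <- generate_budgets(1, seed = 800 + i)
    b <- as_budget(budgets[1, ])
    p <- utility_params("DA_CRRA", beta = runif(1, -0.9, 4),
                        rho = runif(1, 0, 3))
    ob <- optimal_bundle(b, p)
    xs <- seq(0, x_intercept(b), length.out = 1e5)
    ys <- pmax((b$expenditure - b$price_x * xs) / b$price_y, 0)
    v <- subjective_value(xs, ys, p)
    x_dense <- xs[which.max(v)]
    # value at the package optimum is at least the dense-grid value, and
    # the maximizers are close (up to symmetric ties)
    expect_gte(ob$sv, max(v) - 1e-9)
    same_x <- abs(ob$bundle[["x"]] - x_dense) < 0.05
    sym_tie <- abs(subjective_value(x_dense, ys[which.max(v)], p) -
                     ob$sv) < 1e-9
    expect_true(same_x || sym_tie)
  }
})

test_that("money metric: linear closed form and the optimum's own budget", {
  # EV indifference set x + y = 60; cheapest at prices (1,2) is (60,0)
  expect_equal(money_metric(c(20, 40), c(1, 2), ev_params()), 60,
               tolerance = 1e-9)
  # the optimal bundle is the cheapest point on its own level set at the
  # budget's prices, so m equals the expenditure
  set.seed(5)
  for (i in 1:8) {
    budgets <- generate_budgets(1, seed = 900 + i)
    b <- as_budget(budgets[1, ])
    p <- utility_params("DA_CRRA", beta = runif(1, 0, 3),
                        rho = runif(1, 0.1, 2.5))
    ob <- optimal_bundle(b, p)
    m <- money_metric(unname(ob$bundle), c(b$price_x, b$price_y), p)
    expect_equal(m, b$expenditure, tolerance = 1e-4)
  }
})

test_that("money metric matches a dense-scan oracle, convex or not", {
  set.seed(6)
  for (i in 1:10) {
    beta <- runif(1, -1, 4)  # includes the non-convex elation range
    p <- utility_params("DA_CRRA", beta = beta, rho = runif(1, 0, 2.5))
    tgt <- c(runif(1, 1, 80), runif(1, 1, 80))
    px <- runif(1, 0.5, 3); py <- runif(1, 0.5, 3)
    m <- money_metric(tgt, c(px, py), p)
    mb <- brute_money_metric(tgt, px, py, p)
    expect_lt(abs(m - mb) / mb, 2e-3)
    expect_lte(m, px * tgt[1] + py * tgt[2] + 1e-12)
  }
  # beta = -1: the level-set minimum is one of the two axis corners
  pe <- utility_params("DA_CRRA", beta = -1, rho = 0)
  m <- money_metric(c(30, 50), c(2, 1), pe)
  expect_equal(m, min(2, 1) * 50)  # max(x, y) = 50 at the cheap corner
})

test_that("the zero floor for CRRA rho >= 1 keeps corner values finite", {
  p <- utility_params("DA_CRRA", beta = 0, rho = 1)
  expect_true(is.finite(subjective_value(0, 50, p)))
  p2 <- utility_params("DA_CRRA", beta = 0, rho = 2)
  expect_true(is.finite(subjective_value(0, 50, p2)))
  expect_true(is.finite(money_metric(c(0, 50), c(1, 1), p2)))
})
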