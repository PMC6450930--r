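# Disappointment-aversion utility over 50/50 two-account lotteries, the
# optimal bundle on a budget line, and money-metric expenditure minimization.

#' Parametric utility specification
#'
#' Disappointment-aversion (DA) preferences over 50/50 lotteries: the better
#' outcome gets weight `gamma = 1/(2 + beta)` and the worse outcome weight
#' `1 - gamma`, each passed through a curvature index `omega`.  `beta > 0`
#' overweights the worse outcome (disappointment aversion), `beta < 0` the
#' better one (elation seeking); `beta = 0` is expected utility.  The
#' curvature family is either CRRA, `omega(z) = z^(1-rho)/(1-rho)` with
#' `omega(z) = log(z)` at `rho = 1`, or CARA, `omega(z) = 1 - exp(-A z)`.
#'
#' @param family `"DA_CRRA"` or `"DA_CARA"`.
#' @param beta disappointment parameter, `beta >= -1`.
#' @param rho relative risk aversion (>= 0, CRRA family only).
#' @param A absolute risk aversion (> 0, CARA family only).
#' @return an object of class `utility_params`.
#' @examples
#' utility_params("DA_CRRA", beta = 0.5, rho = 0.5)
#' @export
utility_params <- function(family = c("DA_CRRA", "DA_CARA"),
                           beta = 0, rho = NULL, A = NULL) {
  family <- match.arg(family)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < -1)
    stop("beta must be a number >= -1")
  if (family == "DA_CRRA") {
    if (is.null(rho)) stop("DA_CRRA requires rho")
    if (!is.null(A)) stop("DA_CRRA takes no A parameter")
    if (!(rho >= 0)) stop("rho must be >= 0")
  } else {
    if (is.null(A)) stop("DA_CARA requires A")
    if (!is.null(rho)) stop("DA_CARA takes no rho parameter")
    if (!(A > 0)) stop("A must be > 0")
  }
  structure(list(family = family, beta = beta, rho = rho, A = A,
                 gamma = 1 / (2 + beta)),
            class = "utility_params")
}

#' @export
print.utility_params <- function(x, ...) {
  if (x$family == "DA_CRRA")
    cat(sprintf("DA-CRRA utility: beta = %.4g (gamma = %.4g), rho = %.4g\n",
                x$beta, x$gamma, x$rho))
  else
    cat(sprintf("DA-CARA utility: beta = %.4g (gamma = %.4g), A = %.4g\n",
                x$beta, x$gamma, x$A))
  invisible(x)
}

# Curvature index omega, vectorized in z.  For CRRA with rho >= 1 the index
# is undefined at z = 0; amounts are floored at EPS_FLOOR tokens there.
omega <- function(z, params) {
  if (params$family == "DA_CRRA") {
    rho <- params$rho
    if (rho >= 1) z <- pmax(z, EPS_FLOOR)
    if (rho == 1) return(log(z))
    return(z^(1 - rho) / (1 - rho))
  }
  1 - exp(-params$A * z)
}

# Generalized inverse: the smallest z >= 0 with omega(z) >= t, +Inf when no
# such z exists (t above the range supremum).  This is exactly the inner
# solve of the money-metric problem, so out-of-range t must degrade
# gracefully rather than error.
omega_inv <- function(t, params) {
  if (params$family == "DA_CRRA") {
    rho <- params$rho
    if (rho == 1) return(exp(t))
    if (rho < 1) {
      z <- pmax((1 - rho) * t, 0)^(1 / (1 - rho))
      return(z)
    }
    # rho > 1: omega < 0, sup 0
    z <- ifelse(t >= 0, Inf, ((1 - rho) * t)^(1 / (1 - rho)))
    return(pmax(z, 0))
  }
  ifelse(t >= 1, Inf, pmax(-log1p(-pmin(t, 1 - 1e-300)) / params$A, 0))
}

#' Subjective value of a bundle
#'
#' `SV(x, y) = gamma * omega(max(x, y)) + (1 - gamma) * omega(min(x, y))`
#' with `gamma = 1/(2 + beta)`.  Depends on the bundle only through its
#' larger and smaller coordinate, hence is symmetric under swapping the two
#' accounts.  Vectorized over `x` and `y`.
#'
#' @param x,y token allocations (>= 0); `x` may also be a length-2 bundle
#'   when `y` is missing.
#' @param params a [utility_params()] object.
#' @return subjective value(s), in utils.
#' @examples
#' p <- utility_params("DA_CRRA", beta = 0, rho = 0)
#' subjective_value(10, 30, p)  # expected value: 20
#' @export
subjective_value <- function(x, y = NULL, params) {
  if (is.null(y)) {
    if (length(x) != 2L) stop("provide y, or a length-2 bundle in x")
    y <- x[[2]]; x <- x[[1]]
  }
  if (any(x < 0 | y < 0)) stop("bundle coordinates must be >= 0")
  g <- params$gamma
  hi <- omega(pmax(x, y), params)
  if (g == 1) return(hi)  # beta = -1: only the larger amount matters
  g * hi + (1 - g) * omega(pmin(x, y), params)
}

#' Optimal bundle on a budget line
#'
#' Maximizes [subjective_value()] along the line: a 0.1-token grid scan in
#' x augmented with the exact 45-degree (safe) bundle and both corners,
#' followed by golden-section refinement on the bracket around the best grid
#' point.  Ties are broken toward the bundle with larger x.  Deterministic.
#'
#' @param budget a budget set.
#' @param params a [utility_params()] object.
#' @param grid_step scan resolution in tokens.
#' @return list with `bundle` (named `c(x =, y =)`) and `sv`.
#' @export
optimal_bundle <- function(budget, params, grid_step = TOKEN_GRID) {
  b <- as_budget(budget)
  xi <- x_intercept(b)
  on_line_y <- function(x) pmax((b$expenditure - b$price_x * x) / b$price_y, 0)
  f <- function(x) subjective_value(x, on_line_y(x), params)
  xs <- unique(sort(c(seq(0, xi, by = grid_step), xi,
                      min(safe_portfolio(b), xi))))
  v <- f(xs)
  i <- which.max(v)
  lo <- xs[max(i - 1L, 1L)]
  hi <- xs[min(i + 1L, length(xs))]
  cand_x <- c(xs[i], lo, hi)
  if (hi > lo) {
    op <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-9)
    cand_x <- c(cand_x, op$maximum)
  }
  cand_v <- f(cand_x)
  keep <- which(cand_v >= max(cand_v) - 1e-12)
  j <- keep[which.max(cand_x[keep])]  # tie toward larger x
  x_star <- cand_x[j]
  c_bundle <- c(x = x_star, y = unname(on_line_y(x_star)))
  list(bundle = c_bundle,
       sv = unname(subjective_value(c_bundle[[1]], c_bundle[[2]], params)))
}

# Vectorized money metric across trials.  For each target bundle with value
# level u0, the cheapest bundle at prices (px, py) attaining SV >= u0 lies
# on the level boundary, which splits at the 45-degree kink into two smooth
# branches; on the branch where the first coordinate is the larger one,
#   y(x) = omega_inv((u0 - gamma*omega(x)) / (1 - gamma)).
# Candidates: the target itself, the kink bundle, both axis corners, and a
# scanned + locally refined grid on each branch.
money_metric_vec <- function(x, y, px, py, params,
                             n_scan = 33L, refine_passes = 3L,
                             refine_pts = 17L) {
  n <- length(x)
  g <- params$gamma
  u0 <- subjective_value(x, y, params)
  cost_target <- px * x + py * y
  zk <- omega_inv(u0, params)                    # 45-degree kink level bundle
  best <- pmin(cost_target, (px + py) * zk)

  om0 <- omega(0, params)
  zc <- omega_inv((u0 - (1 - g) * om0) / g, params)  # axis corners
  corner_cost <- pmin(px, py) * zc  # Inf when the corner cannot reach u0
  best <- pmin(best, corner_cost)

  if (g < 1) {
    scan_branch <- function(pa, pb) {
      # x runs from the kink to min(corner, cost bound); y = branch inverse
      xhi <- pmin(zc, best / pa)
      xhi <- pmax(xhi, zk)
      lo <- zk; hi <- xhi
      for (pass in seq_len(refine_passes + 1L)) {
        K <- if (pass == 1L) n_scan else refine_pts
        tt <- seq(0, 1, length.out = K)
        xg <- outer(lo, rep(1, K)) + outer(hi - lo, tt)   # n x K
        tg <- (u0 - g * omega(xg, params)) / (1 - g)
        yg <- omega_inv(tg, params)
        cost <- pa * xg + pb * yg
        cost[!is.finite(cost)] <- Inf
        j <- max.col(-cost, ties.method = "first")
        idx <- cbind(seq_len(n), j)
        best <<- pmin(best, cost[idx])
        step <- (hi - lo) / (K - 1)
        xb <- xg[idx]
        lo <- pmax(xb - step, zk)
        hi <- pmin(xb + step, xhi)
      }
      invisible(NULL)
    }
    scan_branch(px, py)
    scan_branch(py, px)
  }
  best
}

#' Money metric: minimal expenditure attaining a bundle's value level
#'
#' The minimal cost, at the given prices, of any bundle whose subjective
#' value is at least that of `target`:
#' `m = min over {u(y) >= u(target)} of p . y`.  Always `m <= p . target`
#' (the target itself is feasible).  Both axis corners and the 45-degree
#' kink of the indifference boundary are evaluated explicitly, so the
#' non-convex elation-seeking case (`beta < 0`) is handled.
#'
#' @param target bundle, named or plain length-2 numeric `c(x, y)`.
#' @param prices a budget set or length-2 numeric `c(price_x, price_y)`
#'   (the expenditure component of a budget set is ignored).
#' @param params a [utility_params()] object.
#' @param n_scan,refine_passes,refine_pts search resolution knobs.
#' @return minimal expenditure, in price units.
#' @examples
#' p <- utility_params("DA_CRRA", beta = 0, rho = 0)
#' money_metric(c(20, 40), c(1, 2), p)  # level x+y = 60, corner (60, 0): 60
#' @export
money_metric <- function(target, prices, params, n_scan = 33L,
                         refine_passes = 3L, refine_pts = 17L) {
  if (inherits(prices, "budget_set") || is.data.frame(prices) ||
      (is.list(prices) && !is.null(prices$price_x))) {
    b <- as_budget(prices)
    px <- b$price_x; py <- b$price_y
  } else {
    if (length(prices) != 2L || any(prices <= 0))
      stop("prices must be a budget set or two positive numbers")
    px <- prices[[1]]; py <- prices[[2]]
  }
  if (length(target) != 2L || any(target < 0))
    stop("target must be a nonnegative length-2 bundle")
  money_metric_vec(target[[1]], target[[2]], px, py, params,
                   n_scan = n_scan, refine_passes = refine_passes,
                   refine_pts = refine_pts)
}
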