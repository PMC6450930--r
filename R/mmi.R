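# Aggregate Money Metric Index with parameter recovery, per-trial
# money-metric adjustments, and the leave-one-out trial-specific indices.

# Estimation box.  Beyond beta = 10 or rho = 10 the implied behavior is
# indistinguishable from max-min / corner choices at 0.1-token resolution;
# A above 1 likewise with token amounts up to 100.
BETA_MAX <- 10
RHO_MAX <- 10
A_MAX <- 1
A_MIN <- 1e-4

#' Per-trial money-metric adjustments
#'
#' For each observation, the normalized inward budget adjustment
#' `v*_i = 1 - m(x^i, p^i, u) / (p^i . x^i)` where `m` is the
#' [money_metric()]: the fraction of expenditure that must be given up
#' before the budget no longer affords anything the utility ranks above the
#' chosen bundle.  Each `v*_i` lies in `[0, 1)`; 0 means the choice is
#' optimal under `params`.
#'
#' @param dataset a [choice_dataset()].
#' @param params a [utility_params()] object.
#' @param ... search knobs passed to the money-metric solver.
#' @return numeric vector of length `n`.
#' @export
mmi_adjustments <- function(dataset, params, ...) {
  ds <- normalize_dataset(dataset)
  m <- money_metric_vec(ds$x, ds$y, ds$price_x, ds$price_y, params, ...)
  spent <- ds$price_x * ds$x + ds$price_y * ds$y
  pmin(pmax(1 - m / spent, 0), 1 - 1e-12)
}

# Aggregated incompatibility of a utility with the (normalized) dataset.
# The default aggregator is the root of the average squared adjustment,
# which keeps the index on the same 0-1 "fraction of expenditure" scale as
# the Afriat index; "mean_sq" gives the raw average of squares.  The two
# are monotone transforms of each other, so the recovered parameters do
# not depend on the choice.
mmi_objective <- function(dataset_norm, params,
                          aggregator = c("rms", "mean_sq"), ...) {
  aggregator <- match.arg(aggregator)
  m <- money_metric_vec(dataset_norm$x, dataset_norm$y,
                        dataset_norm$price_x, dataset_norm$price_y,
                        params, ...)
  spent <- dataset_norm$price_x * dataset_norm$x +
    dataset_norm$price_y * dataset_norm$y
  v <- pmax(1 - m / spent, 0)
  if (aggregator == "rms") sqrt(mean(v^2)) else mean(v^2)
}

# Deterministic coarse parameter grids.  beta always contains the exact
# special points {-1, 0} and rho contains {0, 1} (expected value,
# Cobb-Douglas) so the named special cases are always candidates.
param_grid <- function(family, grid_n = 21L) {
  grid_n <- max(as.integer(grid_n), 5L)
  beta <- unique(sort(c(-1, seq(-0.8, -0.2, length.out = max(grid_n %/% 5, 2L)),
                        0, exp(seq(log(0.05), log(BETA_MAX),
                                   length.out = grid_n - 4L)))))
  if (family == "DA_CRRA") {
    second <- unique(sort(c(0, 1, exp(seq(log(0.05), log(RHO_MAX),
                                          length.out = grid_n - 2L)))))
  } else {
    second <- exp(seq(log(1e-3), log(A_MAX), length.out = grid_n))
  }
  list(beta = beta, second = second)
}

clamp_params <- function(family, par) {
  beta <- min(max(par[1], -1), BETA_MAX)
  if (family == "DA_CRRA") {
    utility_params("DA_CRRA", beta = beta,
                   rho = min(max(par[2], 0), RHO_MAX))
  } else {
    utility_params("DA_CARA", beta = beta,
                   A = min(max(par[2], A_MIN), A_MAX))
  }
}

#' Aggregate Money Metric Index
#'
#' Minimizes the aggregated money-metric adjustments (by default the root
#' of the average squared adjustment) over a parametric utility family: a
#' deterministic coarse grid over the parameter box
#' (`beta` in `[-1, 10]` crossed with `rho` in `[0, 10]` or `A` in
#' `(0, 1]`), followed by Nelder-Mead refinement started from the best
#' `n_starts` grid cells (parameters clamped to the box).  No stochastic
#' restarts, so results are reproducible bit-for-bit.  Returns the best
#' value together with the recovered parameters - the best-fitting utility
#' in the family - and the per-trial adjustments at that optimum.
#'
#' @param dataset a [choice_dataset()].
#' @param family `"DA_CRRA"` or `"DA_CARA"`.
#' @param grid_n approximate points per grid axis.
#' @param n_starts refinement starts taken from the best grid cells.
#' @param refine_maxit Nelder-Mead iteration cap per start.
#' @param aggregator `"rms"` (root of the average squared adjustment; keeps
#'   the index on the same fraction-of-expenditure scale as the Afriat
#'   index) or `"mean_sq"` (the raw average of squares).  Monotone
#'   transforms of each other, so the recovered parameters are identical.
#' @param ... money-metric search knobs.
#' @return list of class `mmi_result`: `aggregate_mmi`, `params`
#'   (a [utility_params()]), `adjustments`, `family`.
#' @examples
#' truth <- utility_params("DA_CRRA", beta = 0.5, rho = 0.5)
#' ds <- simulate_subject(30, "maximize", seed = 3, params = truth)
#' fit <- aggregate_mmi(ds)
#' fit$aggregate_mmi  # ~0: the data are rationalized by the family
#' @export
aggregate_mmi <- function(dataset, family = c("DA_CRRA", "DA_CARA"),
                          grid_n = 21L, n_starts = 3L, refine_maxit = 100L,
                          aggregator = c("rms", "mean_sq"), ...) {
  family <- match.arg(family)
  aggregator <- match.arg(aggregator)
  ds <- normalize_dataset(dataset)
  grd <- param_grid(family, grid_n)
  cells <- expand.grid(beta = grd$beta, second = grd$second,
                       KEEP.OUT.ATTRS = FALSE)
  vals <- vapply(seq_len(nrow(cells)), function(i) {
    mmi_objective(ds, clamp_params(family, as.numeric(cells[i, ])),
                  aggregator = aggregator, ...)
  }, 0)
  ord <- order(vals)
  best_par <- as.numeric(cells[ord[1], ])
  best_val <- vals[ord[1]]
  obj <- function(par) mmi_objective(ds, clamp_params(family, par),
                                     aggregator = aggregator, ...)
  for (s in seq_len(min(n_starts, nrow(cells)))) {
    op <- stats::optim(as.numeric(cells[ord[s], ]), obj,
                       method = "Nelder-Mead",
                       control = list(maxit = refine_maxit, reltol = 1e-8))
    if (op$value < best_val) {
      best_val <- op$value
      best_par <- op$par
    }
  }
  params <- clamp_params(family, best_par)
  structure(list(aggregate_mmi = best_val,
                 params = params,
                 adjustments = mmi_adjustments(dataset, params, ...),
                 family = family,
                 aggregator = aggregator),
            class = "mmi_result")
}

#' @export
print.mmi_result <- function(x, ...) {
  cat(sprintf("aggregate MMI = %.5g (%s)\n", x$aggregate_mmi, x$family))
  print(x$params)
  invisible(x)
}

#' Leave-one-out trial-specific inconsistency index
#'
#' For an aggregate index `eps`, the trial-specific value of observation
#' `i` is `eps(D) - eps(D_{-i})`: the inconsistency the trial contributes
#' to the whole dataset.  Three aggregate indices are supported: the
#' parametric `"mmi"` (utility parameters re-estimated for every
#' `D_{-i}`), and the nonparametric `"afriat"` and `"violations"`.  For the
#' nonparametric indices removal can only relax the revealed-preference
#' relations, so the series is nonnegative; the MMI series can be mildly
#' negative for consistency-anchoring trials because the mean-of-squares
#' denominator shrinks with the trial removed.
#'
#' The `D_{-i}` MMI optimizations warm-start at the full-data optimum and
#' add a reduced grid plus a short refinement (`warm_start = TRUE`, the
#' default approximation used for speed); `exact = TRUE` re-runs the full
#' search for every `D_{-i}`.  The Afriat leave-one-out series uses the
#' exact closed-form `e*` (see [afriat_index()]) so differences are exact.
#'
#' @param dataset a [choice_dataset()] with at least 3 observations.
#' @param index `"mmi"`, `"afriat"` or `"violations"`.
#' @param family utility family for `index = "mmi"`.
#' @param warm_start warm-start the `D_{-i}` searches at the full-data
#'   optimum.
#' @param exact use the full search budget for every `D_{-i}`.
#' @param loo_grid_n,loo_refine_maxit reduced search budget for the
#'   warm-started `D_{-i}` fits.
#' @param mmi_full optional precomputed full-data [aggregate_mmi()] result.
#' @param ... passed to the MMI machinery.
#' @return list of class `trial_index_series`: `index_name`, `values`
#'   (length n), `epsilon_full`, `epsilon_loo`.
#' @export
loo_index <- function(dataset, index = c("mmi", "afriat", "violations"),
                      family = "DA_CRRA", warm_start = TRUE, exact = FALSE,
                      loo_grid_n = 7L, loo_refine_maxit = 40L,
                      mmi_full = NULL, ...) {
  index <- match.arg(index)
  n <- n_obs(dataset)
  if (n < 3L) stop("leave-one-out needs at least 3 observations")

  if (index == "afriat") {
    W <- cost_ratio_matrix(dataset)
    res <- cpp_loo_estar(W)
    eps_full <- 1 - res$e_full
    eps_loo <- 1 - res$e_loo
  } else if (index == "violations") {
    W <- cost_ratio_matrix(dataset)
    eps_full <- nrow(cpp_garp_violation_pairs(W, 1))
    eps_loo <- vapply(seq_len(n), function(i) {
      nrow(cpp_garp_violation_pairs(W[-i, -i, drop = FALSE], 1))
    }, 0)
  } else {
    if (is.null(mmi_full))
      mmi_full <- aggregate_mmi(dataset, family = family, ...)
    eps_full <- mmi_full$aggregate_mmi
    full_par <- if (family == "DA_CRRA")
      c(mmi_full$params$beta, mmi_full$params$rho)
    else c(mmi_full$params$beta, mmi_full$params$A)
    eps_loo <- vapply(seq_len(n), function(i) {
      sub <- choice_dataset(as.data.frame(dataset)[-i, ],
                            subject_id = attr(dataset, "subject_id"),
                            validate = FALSE)
      if (exact) {
        fit <- aggregate_mmi(sub, family = family, ...)
        return(fit$aggregate_mmi)
      }
      fit <- aggregate_mmi(sub, family = family, grid_n = loo_grid_n,
                           n_starts = 1L, refine_maxit = loo_refine_maxit,
                           ...)
      best <- fit$aggregate_mmi
      if (warm_start) {
        dsn <- normalize_dataset(sub)
        agg <- mmi_full$aggregator
        warm <- mmi_objective(dsn, mmi_full$params, aggregator = agg, ...)
        op <- stats::optim(full_par,
                           function(p) mmi_objective(dsn,
                                                     clamp_params(family, p),
                                                     aggregator = agg,
                                                     ...),
                           method = "Nelder-Mead",
                           control = list(maxit = loo_refine_maxit,
                                          reltol = 1e-8))
        best <- min(best, warm, op$value)
      }
      best
    }, 0)
  }
  structure(list(index_name = index,
                 values = eps_full - eps_loo,
                 epsilon_full = eps_full,
                 epsilon_loo = eps_loo),
            class = "trial_index_series")
}

#' @export
print.trial_index_series <- function(x, ...) {
  cat(sprintf("trial-specific %s index: n = %d, aggregate = %.5g\n",
              x$index_name, length(x$values), x$epsilon_full))
  print(summary(x$values))
  invisible(x)
}
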