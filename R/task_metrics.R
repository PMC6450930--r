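# Choice Simplicity index for continuous budget sets, the confidence proxy,
# and the per-trial regressor table.

#' Choice Simplicity index
#'
#' Difficulty scoring for a continuous budget set under a given utility:
#' the line is discretized into `n_points` bundles (uniform in x, corners
#' included), each bundle's subjective value `v_i` is computed, and the
#' index is the mean value gap to the best bundle, normalized by the
#' endowment:
#' `mean(V - v_i) / Endowment`, with `V = max v_i`.  Values near 0 mean the
#' bundles along the line are similarly attractive - a difficult choice;
#' large values mean one region clearly dominates - an easy choice.  The
#' endowment normalization removes over-scoring of longer budget lines;
#' `Endowment` is the safe-portfolio token count
#' `expenditure / (price_x + price_y)` by default (matching the endowment
#' regressor), with raw expenditure as an option since the normalization
#' unit is a modeling choice.
#'
#' @param budget a budget set.
#' @param params a [utility_params()] object.
#' @param n_points discretization (>= 2; 1000 mirrors the reference
#'   implementation of the measure).
#' @param normalize `"safe_portfolio"` (tokens) or `"expenditure"`.
#' @return nonnegative scalar; 0 signals maximal difficulty.
#' @examples
#' p <- utility_params("DA_CRRA", beta = 0, rho = 0)
#' choice_simplicity(budget_set(1, 1, 100), p)  # symmetric line, EV: 0
#' @export
choice_simplicity <- function(budget, params, n_points = 1000L,
                              normalize = c("safe_portfolio",
                                            "expenditure")) {
  normalize <- match.arg(normalize)
  if (!(is.numeric(n_points) && n_points >= 2))
    stop("n_points must be >= 2")
  b <- as_budget(budget)
  xi <- x_intercept(b)
  if (!(xi > 0 && y_intercept(b) > 0)) stop("degenerate budget line")
  xs <- seq(0, xi, length.out = as.integer(n_points))
  ys <- pmax((b$expenditure - b$price_x * xs) / b$price_y, 0)
  v <- subjective_value(xs, ys, params)
  denom <- if (normalize == "safe_portfolio") safe_portfolio(b)
  else b$expenditure
  (max(v) - mean(v)) / denom
}

#' Per-trial regressor table
#'
#' Assembles the trial-level design matrix used to relate behavior (or a
#' neural signal) to inconsistency: response time, trial-specific MMI,
#' subjective value of the chosen bundle at the recovered parameters, log
#' price ratio, endowment (safe-portfolio tokens), choice simplicity, and
#' the confidence proxy (squared subjective value, the second-order
#' polynomial term of SV).
#'
#' @param dataset a [choice_dataset()].
#' @param mmi_result an [aggregate_mmi()] fit on the same dataset
#'   (supplies the recovered utility parameters).
#' @param loo_series a [loo_index()] series on the same dataset (the
#'   `trial_mmi` column); computed on the fly when `NULL`.
#' @param n_points simplicity discretization.
#' @param ... passed to [loo_index()] when it must be computed.
#' @return data frame with one row per trial and columns `trial`, `rt`,
#'   `trial_mmi`, `sv`, `price_ratio`, `endowment`, `simplicity`,
#'   `confidence`.
#' @export
regressor_table <- function(dataset, mmi_result, loo_series = NULL,
                            n_points = 1000L, ...) {
  n <- n_obs(dataset)
  if (is.null(loo_series))
    loo_series <- loo_index(dataset, "mmi", family = mmi_result$family,
                            mmi_full = mmi_result, ...)
  if (length(loo_series$values) != n)
    stop("loo_series length does not match the dataset")
  params <- mmi_result$params
  sv <- subjective_value(dataset$x, dataset$y, params)
  simp <- vapply(seq_len(n), function(k) {
    choice_simplicity(dataset[k, ], params, n_points = n_points)
  }, 0)
  data.frame(trial = dataset$trial,
             rt = dataset$rt,
             trial_mmi = loo_series$values,
             sv = sv,
             price_ratio = log(dataset$price_x / dataset$price_y),
             endowment = dataset$expenditure /
               (dataset$price_x + dataset$price_y),
             simplicity = simp,
             confidence = sv^2)
}
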