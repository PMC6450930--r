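# Domain types, the tabular dataset format, and the synthetic task generator.

#' Construct a budget set
#'
#' A linear budget line over two accounts: positive per-token prices and a
#' total expenditure.  The feasible bundles are \{(x, y) >= 0 :
#' price_x * x + price_y * y = expenditure\}.
#'
#' @param price_x,price_y price per token of account X / Y (> 0).
#' @param expenditure total budget in price units (> 0).
#' @return an object of class `budget_set`.
#' @examples
#' b <- budget_set(1, 2, 100)   # x-intercept 100, y-intercept 50
#' x_intercept(b)
#' @export
budget_set <- function(price_x, price_y, expenditure) {
  if (!is.numeric(price_x) || !is.numeric(price_y) || !is.numeric(expenditure) ||
      length(price_x) != 1L || length(price_y) != 1L || length(expenditure) != 1L)
    stop("price_x, price_y and expenditure must be numeric scalars")
  if (!(price_x > 0 && price_y > 0 && expenditure > 0))
    stop("prices and expenditure must be strictly positive")
  structure(list(price_x = price_x, price_y = price_y,
                 expenditure = expenditure),
            class = "budget_set")
}

#' @rdname budget_set
#' @param b a `budget_set` (or anything [as_budget()] accepts).
#' @export
x_intercept <- function(b) { b <- as_budget(b); b$expenditure / b$price_x }

#' @rdname budget_set
#' @export
y_intercept <- function(b) { b <- as_budget(b); b$expenditure / b$price_y }

#' @rdname budget_set
#' @export
log_price_ratio <- function(b) { b <- as_budget(b); log(b$price_x / b$price_y) }

#' @rdname budget_set
#' @details `safe_portfolio()` is the token amount of the riskless bundle on
#'   the 45-degree line, `expenditure / (price_x + price_y)`; it doubles as
#'   the endowment regressor.
#' @export
safe_portfolio <- function(b) {
  b <- as_budget(b)
  b$expenditure / (b$price_x + b$price_y)
}

#' Coerce to a budget set
#'
#' Accepts a `budget_set`, a numeric vector `c(price_x, price_y, expenditure)`,
#' or a one-row data frame with those columns.
#' @param b object to coerce.
#' @export
as_budget <- function(b) {
  if (inherits(b, "budget_set")) return(b)
  if (is.numeric(b) && length(b) == 3L) return(budget_set(b[1], b[2], b[3]))
  if (is.data.frame(b) && nrow(b) == 1L)
    return(budget_set(b$price_x, b$price_y, b$expenditure))
  if (is.list(b) && all(c("price_x", "price_y", "expenditure") %in% names(b)))
    return(budget_set(b$price_x, b$price_y, b$expenditure))
  stop("cannot interpret object as a budget set")
}

#' @export
print.budget_set <- function(x, ...) {
  cat(sprintf("budget set: p = (%.6g, %.6g), expenditure %.6g (intercepts %.6g / %.6g)\n",
              x$price_x, x$price_y, x$expenditure,
              x_intercept(x), y_intercept(x)))
  invisible(x)
}

# Deterministic per-trial substream seed, so trial k of a simulated subject
# is reproducible independently of the number of trials requested.
trial_seed <- function(seed, k, stream = 0L) {
  s <- (abs(as.numeric(seed)) %% 1000000007) + 104729 * as.numeric(k) +
    999983 * as.numeric(stream)
  as.integer(s %% 2147483629)
}

#' Generate randomized budget lines for the two-account allocation task
#'
#' Emulates the graphical budget-line task: axes scaled 0--100 tokens at
#' 0.1-token resolution, slopes and endowments randomized per trial.  Each
#' intercept is drawn uniformly on the 0.1-token grid in
#' `[1, max_intercept]`, redrawing until the larger of the two intercepts is
#' at least `min_major_intercept`.  Prices are normalized so that the
#' expenditure is 1 (`price_x = 1/x-intercept`, `price_y = 1/y-intercept`);
#' all indices in the package are invariant to this scale choice.
#'
#' @param n_trials number of budget lines (>= 1).
#' @param seed integer seed; each trial consumes its own substream.
#' @param min_major_intercept lower bound (tokens) on the larger intercept.
#' @param max_intercept upper bound (tokens) on both intercepts.
#' @return data frame with columns `price_x`, `price_y`, `expenditure`,
#'   `x_intercept`, `y_intercept`; one row per trial.
#' @examples
#' head(generate_budgets(5, seed = 1))
#' @export
generate_budgets <- function(n_trials, seed, min_major_intercept = 50,
                             max_intercept = 100) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("n_trials must be a positive count")
  if (!(max_intercept >= min_major_intercept && min_major_intercept > 0))
    stop("need max_intercept >= min_major_intercept > 0")
  n_trials <- as.integer(n_trials)
  grid <- seq.int(10L, as.integer(round(max_intercept * 10)))
  xi <- yi <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    set.seed(trial_seed(seed, k, stream = 0L))
    repeat {
      a <- grid[sample.int(length(grid), 2L, replace = TRUE)] / 10
      if (max(a) >= min_major_intercept) break
    }
    xi[k] <- a[1]; yi[k] <- a[2]
  }
  data.frame(price_x = 1 / xi, price_y = 1 / yi, expenditure = 1,
             x_intercept = xi, y_intercept = yi)
}

# Discretized bundles along a budget line: 0.1-token steps in x from 0 to
# the x-intercept (mirrors the task resolution).
line_grid <- function(budget, step = TOKEN_GRID) {
  b <- as_budget(budget)
  xi <- x_intercept(b)
  xs <- seq(0, floor(xi / step + 1e-9) * step, by = step)
  ys <- (b$expenditure - b$price_x * xs) / b$price_y
  ys[ys < 0] <- 0
  list(x = xs, y = ys)
}

#' Synthetic chooser strategies
#'
#' Picks a bundle on a budget line according to a named strategy:
#' \describe{
#'   \item{`uniform_random`}{uniform over the 0.1-token discretized line.}
#'   \item{`safe_45`}{the riskless bundle `x = y` on the 45-degree line.}
#'   \item{`cheaper_corner`}{the whole budget on the cheaper account (X on a
#'     price tie).}
#'   \item{`expenditure_split`}{equal expenditure on both accounts
#'     (Cobb--Douglas behavior).}
#'   \item{`maximize`}{the bundle maximizing `subjective_value()` under
#'     `params` (noiseless utility maximization; such data satisfy GARP).}
#'   \item{`nrum`}{random-utility choice: argmax of value plus one skewed
#'     noise draw per grid bundle (see [nrum_simulate()]).}
#' }
#'
#' @param budget a budget set.
#' @param strategy one of the strategies above.
#' @param seed integer seed (used by the stochastic strategies).
#' @param params a [utility_params()] object (`maximize`, `nrum`).
#' @param noise a [noise_spec()] object (`nrum`).
#' @return named numeric `c(x =, y =)` lying on the budget line.
#' @export
choose_bundle <- function(budget,
                          strategy = c("uniform_random", "safe_45",
                                       "cheaper_corner", "expenditure_split",
                                       "maximize", "nrum"),
                          seed = NULL, params = NULL, noise = NULL) {
  strategy <- match.arg(strategy)
  b <- as_budget(budget)
  if (strategy == "uniform_random") {
    g <- line_grid(b)
    if (!is.null(seed)) set.seed(seed)
    i <- sample.int(length(g$x), 1L)
    return(c(x = g$x[i], y = g$y[i]))
  }
  if (strategy == "safe_45") {
    z <- safe_portfolio(b)
    return(c(x = z, y = z))
  }
  if (strategy == "cheaper_corner") {
    if (b$price_x <= b$price_y)
      return(c(x = x_intercept(b), y = 0))
    return(c(x = 0, y = y_intercept(b)))
  }
  if (strategy == "expenditure_split") {
    return(c(x = b$expenditure / (2 * b$price_x),
             y = b$expenditure / (2 * b$price_y)))
  }
  if (strategy == "maximize") {
    if (is.null(params)) stop("strategy 'maximize' needs utility params")
    return(optimal_bundle(b, params)$bundle)
  }
  # nrum
  if (is.null(params) || is.null(noise))
    stop("strategy 'nrum' needs utility params and a noise spec")
  sim <- nrum_simulate(data.frame(price_x = b$price_x, price_y = b$price_y,
                                  expenditure = b$expenditure),
                       params, noise, seed = if (is.null(seed)) 1L else seed)
  ch <- sim$dataset
  c(x = ch$x[1], y = ch$y[1])
}

#' Construct a choice dataset
#'
#' The unit of analysis: an ordered set of observations (budget line plus
#' chosen bundle, optionally a response time) for one subject.  Trial order
#' is preserved; leave-one-out indexing is positional.
#'
#' @param trials data frame with columns `price_x`, `price_y`, `expenditure`,
#'   `x`, `y` and optionally `trial` and `rt` (seconds).
#' @param subject_id subject label.
#' @param tol_budget relative tolerance for the on-line invariant
#'   `price_x*x + price_y*y = expenditure`.
#' @param validate check positivity and the on-line invariant.
#' @return data frame of class `choice_dataset` with attribute `subject_id`.
#' @export
choice_dataset <- function(trials, subject_id = "S1",
                           tol_budget = TOL_BUDGET, validate = TRUE) {
  need <- c("price_x", "price_y", "expenditure", "x", "y")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  trials <- as.data.frame(trials)
  if (is.null(trials$trial)) trials$trial <- seq_len(nrow(trials))
  if (is.null(trials$rt)) trials$rt <- NA_real_
  trials <- trials[c("trial", "price_x", "price_y", "expenditure",
                     "x", "y", "rt")]
  if (validate) {
    bad_pos <- which(!(trials$price_x > 0 & trials$price_y > 0 &
                         trials$expenditure > 0 &
                         trials$x >= 0 & trials$y >= 0))
    if (length(bad_pos))
      stop("non-positive prices/expenditure or negative bundle in row(s) ",
           paste(bad_pos, collapse = ", "))
    resid <- abs(trials$price_x * trials$x + trials$price_y * trials$y -
                   trials$expenditure) / trials$expenditure
    off <- which(resid > tol_budget)
    if (length(off))
      stop("chosen bundle off the budget line in row(s) ",
           paste(off, collapse = ", "))
  }
  rownames(trials) <- NULL
  structure(trials, class = c("choice_dataset", "data.frame"),
            subject_id = subject_id)
}

#' @export
print.choice_dataset <- function(x, ...) {
  cat(sprintf("choice dataset '%s': %d trials\n",
              attr(x, "subject_id"), nrow(x)))
  NextMethod()
}

n_obs <- function(dataset) nrow(dataset)

# Rescale every trial so expenditure = 1; indices only depend on this
# normalized representation (prices are identified up to scale).
normalize_dataset <- function(dataset) {
  m <- dataset$expenditure
  dataset$price_x <- dataset$price_x / m
  dataset$price_y <- dataset$price_y / m
  dataset$expenditure <- 1
  dataset
}

#' Simulate one subject's session
#'
#' Generates `n_trials` randomized budget lines (see [generate_budgets()])
#' and a choice on each line under the given strategy.  Budget draws and
#' choice draws consume distinct per-trial substreams of `seed`.
#'
#' @inheritParams choose_bundle
#' @param n_trials number of trials (the task default is 108).
#' @param seed integer seed.
#' @param subject_id subject label.
#' @param min_major_intercept,max_intercept passed to [generate_budgets()].
#' @return a [choice_dataset()].
#' @examples
#' ds <- simulate_subject(10, strategy = "uniform_random", seed = 42)
#' garp_violations(ds)$n_violations
#' @export
simulate_subject <- function(n_trials = 108,
                             strategy = "uniform_random",
                             seed = 1L, params = NULL, noise = NULL,
                             subject_id = sprintf("sim-%s-%d", strategy, seed),
                             min_major_intercept = 50, max_intercept = 100) {
  budgets <- generate_budgets(n_trials, seed, min_major_intercept,
                              max_intercept)
  xs <- ys <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    ch <- choose_bundle(budgets[k, ], strategy,
                        seed = trial_seed(seed, k, stream = 1L),
                        params = params, noise = noise)
    xs[k] <- ch[["x"]]; ys[k] <- ch[["y"]]
  }
  # choices are constructed on the line; snap exactly onto it in y,
  # clamping the roundoff-negative corner case back to 0
  ys_exact <- (budgets$expenditure - budgets$price_x * xs) / budgets$price_y
  snap <- abs(ys - ys_exact) < 1e-9
  ys[snap] <- ys_exact[snap]
  ys[ys < 0 & ys > -1e-9] <- 0
  choice_dataset(data.frame(price_x = budgets$price_x,
                            price_y = budgets$price_y,
                            expenditure = budgets$expenditure,
                            x = xs, y = ys),
                 subject_id = subject_id)
}

fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.15g", v))

#' Read / write a choice dataset as CSV
#'
#' The on-disk format has header `trial,price_x,price_y,expenditure,x,y,rt`
#' (one row per trial, `rt` may be empty).  Rows whose bundle lies off the
#' budget line beyond `tol_budget` are dropped with a per-row warning
#' (mirroring the exclusion of no-choice trials from a session); structural
#' problems (missing columns, non-positive prices) are errors.  Writing uses
#' a canonical numeric format so `write(read(f))` is byte-identical for
#' files the package wrote.
#'
#' @param path CSV file path.
#' @param subject_id subject label (defaults to the file name).
#' @param tol_budget relative on-line tolerance.
#' @return [read_choice_dataset()]: a `choice_dataset`;
#'   [write_choice_dataset()]: `path`, invisibly.
#' @export
read_choice_dataset <- function(path, subject_id = basename(path),
                                tol_budget = TOL_BUDGET) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "price_x", "price_y", "expenditure", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$rt)) df$rt <- NA_real_
  df$rt <- suppressWarnings(as.numeric(df$rt))
  bad_pos <- which(!(df$price_x > 0 & df$price_y > 0 & df$expenditure > 0))
  if (length(bad_pos))
    stop("non-positive price/expenditure in row(s) ",
         paste(bad_pos, collapse = ", "))
  resid <- abs(df$price_x * df$x + df$price_y * df$y - df$expenditure) /
    df$expenditure
  off <- which(!(df$x >= 0 & df$y >= 0) | resid > tol_budget)
  if (length(off)) {
    warning(sprintf("dropping %d row(s) with bundles off the budget line: %s",
                    length(off), paste(off, collapse = ", ")))
    df <- df[-off, , drop = FALSE]
  }
  choice_dataset(df, subject_id = subject_id, tol_budget = tol_budget)
}

#' @rdname read_choice_dataset
#' @param dataset a `choice_dataset`.
#' @export
write_choice_dataset <- function(dataset, path) {
  cols <- c("trial", "price_x", "price_y", "expenditure", "x", "y", "rt")
  rows <- vapply(seq_len(nrow(dataset)), function(i) {
    paste(vapply(cols, function(cl) fmt_num(dataset[[cl]][i]), ""),
          collapse = ",")
  }, "")
  writeLines(c(paste(cols, collapse = ","), rows), path)
  invisible(path)
}
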