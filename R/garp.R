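# GARP testing at efficiency level e, violation counting, and the Afriat
# critical-cost-efficiency index.

# Cost-ratio matrix W[i, j] = (p^i . x^j) / (p^i . x^i): the cost of bundle
# j at trial i's prices, relative to what was actually spent in trial i.
# Every revealed-preference statement at level e reduces to a comparison
# of W with e, so W is the only input the C++ core needs.
cost_ratio_matrix <- function(dataset) {
  if (n_obs(dataset) < 2L)
    stop("need at least 2 observations")
  P <- cbind(dataset$price_x, dataset$price_y)
  X <- cbind(dataset$x, dataset$y)
  C <- P %*% t(X)
  E <- rowSums(P * X)
  if (any(E <= 0)) stop("zero expenditure on some trial")
  C / E
}

#' Revealed-preference relations at efficiency level e
#'
#' Builds the direct relation `R0` (`e * p^i.x^i >= p^i.x^j`), its strict
#' part `P0` (strict inequality), and the transitive closure `R` of `R0`.
#' At `e = 1` these are the standard revealed-preference relations; lower
#' `e` uniformly deflates every budget, shrinking the relations.
#'
#' @param dataset a [choice_dataset()].
#' @param e efficiency level in `[0, 1]`.
#' @return list of class `relation_matrices` with logical n x n matrices
#'   `R0`, `P0`, `R` and the level `e`.
#' @export
rp_relations <- function(dataset, e = 1) {
  if (!(is.numeric(e) && length(e) == 1L && e >= 0 && e <= 1))
    stop("e must be a scalar in [0, 1]")
  W <- cost_ratio_matrix(dataset)
  R0 <- W <= e
  P0 <- W < e
  # transitive closure by repeated boolean squaring
  R <- R0
  repeat {
    R2 <- (R %*% R > 0) | R
    if (identical(R2, R)) break
    R <- R2
  }
  structure(list(R0 = R0, P0 = P0, R = R, e = e),
            class = "relation_matrices")
}

#' Count GARP violations
#'
#' A dataset satisfies GARP at level `e` when no ordered pair has
#' `x^i R x^j` together with `x^j P0 x^i`.  Violations are counted once per
#' ordered pair, so a mutual strict 2-cycle contributes 2.
#'
#' @inheritParams rp_relations
#' @return list of class `garp_report`: `n_violations`, `violating_pairs`
#'   (two-column matrix of ordered pairs), `satisfied`, `e_level`.
#' @examples
#' toy <- choice_dataset(data.frame(price_x = c(1, 2), price_y = c(2, 1),
#'                                  expenditure = 100,
#'                                  x = c(20, 40), y = c(40, 20)))
#' garp_violations(toy)$n_violations  # 2: both ordered pairs of the cycle
#' @export
garp_violations <- function(dataset, e = 1) {
  if (!(is.numeric(e) && length(e) == 1L && e >= 0 && e <= 1))
    stop("e must be a scalar in [0, 1]")
  W <- cost_ratio_matrix(dataset)
  pairs <- cpp_garp_violation_pairs(W, e)
  colnames(pairs) <- c("i", "j")
  structure(list(n_violations = nrow(pairs),
                 violating_pairs = pairs,
                 satisfied = nrow(pairs) == 0L,
                 e_level = e),
            class = "garp_report")
}

#' @export
print.garp_report <- function(x, ...) {
  cat(sprintf("GARP at e = %.4g: %s (%d violating ordered pair%s)\n",
              x$e_level, if (x$satisfied) "satisfied" else "violated",
              x$n_violations, if (x$n_violations == 1L) "" else "s"))
  invisible(x)
}

#' Afriat critical-cost-efficiency index
#'
#' `1 - e*`, where `e*` is the supremal efficiency level at which the
#' e-adjusted data satisfy GARP.  0 for consistent data; larger values mean
#' budgets must be deflated further before the choices can be rationalized.
#' GARP(e) is monotone in `e` (relations shrink as `e` falls), so `e*` can
#' be found by bisection (the default, reported at the midpoint of the
#' final bracket).  `method = "exact"` instead computes `e*` in closed form
#' as the smallest pairwise violation threshold
#' `max(B[i,j], W[j,i])` over ordered pairs, where `B` is the minimax-path
#' closure of the cost-ratio matrix `W`; the two methods agree to `tol`.
#'
#' @param dataset a [choice_dataset()].
#' @param tol bisection tolerance on `e*`.
#' @param method `"bisection"` or `"exact"`.
#' @return scalar index in `[0, 1]`.
#' @examples
#' ds <- simulate_subject(20, "uniform_random", seed = 7)
#' afriat_index(ds)
#' @export
afriat_index <- function(dataset, tol = 1e-4,
                         method = c("bisection", "exact")) {
  method <- match.arg(method)
  W <- cost_ratio_matrix(dataset)
  if (method == "exact") return(1 - cpp_afriat_estar(W))
  if (cpp_garp_satisfied(W, 1)) return(0)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cpp_garp_satisfied(W, mid)) lo <- mid else hi <- mid
  }
  1 - (lo + hi) / 2
}
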