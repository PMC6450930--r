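# Shared fixtures, built in code.

# Two crossing budget lines whose choices form a strict mutual cycle:
# each bundle costs 80 at the other trial's prices while 100 was spent.
crossing_toy <- function() {
  choice_dataset(data.frame(price_x = c(1, 2), price_y = c(2, 1),
                            expenditure = 100,
                            x = c(20, 40), y = c(40, 20)),
                 subject_id = "crossing-toy")
}

# The crossing pair embedded among 8 consistent corner choosers whose
# pairwise revealed preferences are either absent or one-directional, so
# the only GARP violations are the toy pair's two ordered pairs.
embedded_toy <- function() {
  cons <- data.frame(price_x = c(1, 1, 1, 1, 2, 3, 4, 5) / 10,
                     price_y = c(2, 3, 4, 5, 1, 1, 1, 1) / 10,
                     expenditure = 1)
  cons$x <- c(1 / cons$price_x[1:4], rep(0, 4))
  cons$y <- c(rep(0, 4), 1 / cons$price_y[5:8])
  toy <- data.frame(price_x = c(1, 2) / 100, price_y = c(2, 1) / 100,
                    expenditure = 1, x = c(20, 40), y = c(40, 20))
  choice_dataset(rbind(toy, cons), subject_id = "embedded-toy")
}

ev_params <- function() utility_params("DA_CRRA", beta = 0, rho = 0)

# Independent reachability oracle: exhaustive path enumeration (DFS over
# simple paths), usable for small n only.
brute_reachable <- function(adj) {
  n <- nrow(adj)
  reach <- matrix(FALSE, n, n)
  for (s in seq_len(n)) {
    visit <- function(v, seen) {
      for (w in seq_len(n)) {
        if (adj[v, w] && !seen[w]) {
          reach[s, w] <<- TRUE
          seen[w] <- TRUE
          visit(w, seen)
        } else if (adj[v, w]) {
          reach[s, w] <<- TRUE
        }
      }
    }
    visit(s, rep(FALSE, n))
  }
  reach
}

# Brute-force ordered-pair GARP violation count from first principles.
brute_violations <- function(dataset, e = 1) {
  P <- cbind(dataset$price_x, dataset$price_y)
  X <- cbind(dataset$x, dataset$y)
  C <- P %*% t(X)
  E <- rowSums(P * X)
  R0 <- sweep(C, 1, e * E, "<=")
  P0 <- sweep(C, 1, e * E, "<")
  R <- brute_reachable(R0)
  cnt <- 0L
  for (i in seq_len(nrow(R0))) for (j in seq_len(nrow(R0)))
    if (i != j && R[i, j] && P0[j, i]) cnt <- cnt + 1L
  cnt
}

# Dense-scan money-metric oracle: fine grid over x with a bisection in y.
brute_money_metric <- function(target, px, py, params, n_x = 20000,
                               x_max = NULL) {
  u0 <- subjective_value(target[1], target[2], params)
  if (is.null(x_max)) x_max <- 3 * (px * target[1] + py * target[2]) / px
  xs <- seq(0, x_max, length.out = n_x)
  lo <- rep(0, n_x)
  hi <- rep(3 * (px * target[1] + py * target[2]) / py + x_max, n_x)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    ok <- subjective_value(xs, mid, params) >= u0
    hi[ok] <- mid[ok]
    lo[!ok] <- mid[!ok]
  }
  feas <- subjective_value(xs, hi, params) >= u0 - 1e-10
  min(c(px * xs[feas] + py * hi[feas], px * target[1] + py * target[2]))
}
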