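# Independent oracles: deliberately naive implementations used only to
# cross-check package results on small inputs.

# interval lookup by explicit linear search over [b_i, b_{i+1}) intervals,
# clamping below the first breakpoint
oracle_step_points <- function(value, breakpoints, points) {
  vapply(value, function(v) {
    if (v < breakpoints[1]) return(points[1])
    for (i in rev(seq_along(breakpoints))) {
      if (v >= breakpoints[i]) return(points[i])
    }
  }, numeric(1))
}

# exhaustive pair counting for the concordance statistic
oracle_c_statistic <- function(pred, outcome) {
  ev <- pred[outcome]
  ne <- pred[!outcome]
  total <- 0
  for (x in ev) for (y in ne) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(ev) * length(ne))
}

# equal-count bins via an explicit rank sort with stable tie order
oracle_deciles <- function(x, g = 10) {
  n <- length(x)
  ord <- order(x, seq_along(x))  # stable: original index breaks ties
  sizes <- rep(n %/% g, g) + c(rep(1, n %% g), rep(0, g - n %% g))
  labels <- rep(seq_len(g), times = sizes)
  out <- integer(n)
  out[ord] <- labels
  out
}

# Bernoulli log-likelihood for a coefficient vector (intercept first)
loglik_logistic <- function(beta, x, y) {
  lp <- beta[1] + drop(x %*% beta[-1])
  sum(y * lp - log1p(exp(lp)))
}

# coarse-to-fine grid maximisation of the logistic likelihood; independent
# of IRLS. Shrinks a grid around the running maximiser.
oracle_logistic_grid <- function(x, y, lower = -3, upper = 3,
                                 levels = 14, pts = 11) {
  k <- ncol(x) + 1
  centre <- rep(0, k)
  half <- (upper - lower) / 2
  for (lv in seq_len(levels)) {
    grids <- lapply(seq_len(k), function(j) {
      seq(centre[j] - half, centre[j] + half, length.out = pts)
    })
    best <- -Inf
    best_beta <- centre
    combos <- as.matrix(do.call(expand.grid, grids))
    for (r in seq_len(nrow(combos))) {
      ll <- loglik_logistic(combos[r, ], x, y)
      if (ll > best) {
        best <- ll
        best_beta <- combos[r, ]
      }
    }
    centre <- best_beta
    half <- half * 2 / (pts - 1)  # keep the refined grid overlapping
  }
  unname(centre)
}

# crude (unstratified) risk ratio
oracle_crude_rr <- function(a, n1, b, n0) (a / n1) / (b / n0)
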