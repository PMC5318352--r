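# Shared generators and oracles.

# random generalized fuzzy number; strict = TRUE forces strictly increasing
# knots (non-degenerate legs), needed for the membership/cut round trip
random_gfn <- function(strict = FALSE) {
  k <- sort(stats::runif(4, -10, 10))
  if (strict) {
    while (k[2] - k[1] < 1e-3 || k[4] - k[3] < 1e-3) k <- sort(stats::runif(4, -10, 10))
  }
  gfn(k[1], k[2], k[3], k[4], height = stats::runif(1, 0.05, 1))
}

# per-leg interpolation oracle for the alpha-cut of a trapezoid: solve
# mu(x) = alpha on each leg independently of the alpha_cut() arithmetic
leg_cut_oracle <- function(g, alpha) {
  if (alpha > g$w) return(NULL)
  lo <- if (g$b > g$a) {
    stats::uniroot(function(x) membership(g, x) - alpha,
                   lower = g$a, upper = g$b, tol = 1e-12)$root
  } else g$a
  hi <- if (g$d > g$c) {
    stats::uniroot(function(x) membership(g, x) - alpha,
                   lower = g$c, upper = g$d, tol = 1e-12)$root
  } else g$d
  c(lo, hi)
}

# enumerate the variance of every endpoint selection (2^n), population divisor
enumerate_selection_vars <- function(lo, hi) {
  n <- length(lo)
  sel <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  apply(sel, 1, function(s) {
    x <- ifelse(as.logical(s), hi, lo)
    mean((x - mean(x))^2)
  })
}

arsenic_family <- function(n_mc = 1000, seed = 42) {
  propagate(arsenic_model(), n_mc = n_mc, seed = seed)
}
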