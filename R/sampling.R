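# Probabilistic parameters: distribution specs, inverse-transform Monte Carlo
# sampling, empirical CDFs with the generalized-inverse quantile convention.

#' Distribution specifications for probabilistic model parameters
#'
#' Aleatory (variability) parameters are described by probability
#' distributions and propagated by Monte Carlo. Two families are supported:
#' normal, and a degenerate constant (which lets fixed parameters flow
#' through the probabilistic path unchanged).
#'
#' @param mean,sd Mean and standard deviation of the normal distribution, in
#'   the parameter's units; `sd` must be strictly positive.
#' @param value The constant's value.
#' @return An object of class `"dist_spec"`.
#' @examples
#' dist_normal(70, 5)    # body weight, kg
#' dist_constant(170)    # fish ingestion rate, g/day
#' @export
dist_normal <- function(mean, sd) {
  if (!is.finite(sd) || sd <= 0) stop("sd > 0 required", call. = FALSE)
  structure(list(family = "normal", mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "dist_spec")
}

#' @rdname dist_normal
#' @export
dist_constant <- function(value) {
  stopifnot(is.finite(value))
  structure(list(family = "constant", value = as.numeric(value)),
            class = "dist_spec")
}

#' Draw a reproducible Monte Carlo sample from a distribution spec
#'
#' Sampling is by inverse transform: `n` uniform draws on `[0, 1]` are pushed
#' through the analytic quantile function. This mirrors the construction used
#' by the hybrid engine, where one uniform stream per probabilistic parameter
#' is drawn once and reused across all membership levels.
#'
#' @param spec A [dist_normal()] or [dist_constant()] spec.
#' @param n Number of draws, at least 1.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return Numeric vector of length `n` of class `"sample_set"`, with the
#'   seed attached as an attribute.
#' @export
sample_dist <- function(spec, n, seed) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  set.seed(as.integer(seed))
  u <- stats::runif(n)
  structure(quantile(spec, u), class = "sample_set", seed = as.integer(seed))
}

#' Quantile of a distribution spec or empirical CDF
#'
#' For a distribution spec the analytic quantile (`mean + qnorm(p) * sd` for
#' the normal family); for an empirical CDF the generalized inverse
#' `inf{x : F(x) >= p}`, i.e. the type-1 sample quantile, consistent with the
#' right-continuous step definition of the empirical CDF.
#'
#' @param x A `"dist_spec"` or an `"ecdf_t1"` object from [ecdf_of()].
#' @param probs Probabilities in `(0, 1)` (vectorized).
#' @param ... Unused.
#' @return Numeric vector of quantiles.
#' @examples
#' quantile(dist_normal(70, 5), 0.05)   # 61.77575
#' quantile(ecdf_of(c(1, 2, 3)), 0.5)   # 2
#' @export
quantile.dist_spec <- function(x, probs, ...) {
  stopifnot(all(probs > 0 & probs < 1))
  switch(x$family,
    normal = x$mean + stats::qnorm(probs) * x$sd,
    constant = rep(x$value, length(probs))
  )
}

#' Empirical CDF with the generalized-inverse quantile convention
#'
#' Wraps [stats::ecdf()] (right-continuous step function, step height `1/n`
#' at each order statistic) and tags the result so that [quantile()] on it
#' uses the type-1 (generalized inverse) convention rather than the
#' interpolating default.
#'
#' @param x Non-empty numeric vector of finite values.
#' @return A function of class `c("ecdf_t1", "ecdf", ...)`: evaluates the
#'   empirical CDF; supports `quantile()` and `knots()`.
#' @export
ecdf_of <- function(x) {
  if (length(x) == 0) stop("empty sample", call. = FALSE)
  stopifnot(all(is.finite(x)))
  F <- stats::ecdf(x)
  class(F) <- c("ecdf_t1", class(F))
  F
}

#' @rdname ecdf_of
#' @param probs Probabilities in `(0, 1)`.
#' @param ... Unused.
#' @export
quantile.ecdf_t1 <- function(x, probs, ...) {
  stopifnot(all(probs > 0 & probs < 1))
  unname(stats::quantile(environment(x)$x, probs = probs, type = 1))
}

#' Tidy an empirical CDF into step coordinates
#'
#' @param x An `"ecdf_t1"` object.
#' @param ... Unused.
#' @return A tibble with columns `value` (sorted unique sample values) and
#'   `cumprob` (the CDF evaluated there).
#' @export
tidy.ecdf_t1 <- function(x, ...) {
  k <- stats::knots(x)
  tibble::tibble(value = k, cumprob = x(k))
}
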