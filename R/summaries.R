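# P-boxes and fractile membership functions read from a CDF family, plus
# sharp bounds on the sample variance of interval-valued data.

#' Probability box of a CDF family
#'
#' The p-box is the bounding pair of CDFs of one pass of the family: the
#' ECDF of the per-draw corner minima (left/upper bounding curve) and of the
#' maxima (right/lower curve), both taken at alpha = 0 — the widest cuts,
#' which dominate every other level by alpha-cut nesting.
#'
#' @param family A `"cdf_family"` from [propagate()].
#' @param pass `"umf"` or `"lmf"`: which family the box bounds.
#' @return An object of class `"pbox"` holding the per-draw minima and
#'   maxima, the pass label, and the model (for analytic-quantile
#'   summaries). Summaries are computed by [pbox_range()], [pbox_mean()],
#'   [pbox_variance()] and collected by [glance()].
#' @examples
#' fam <- propagate(arsenic_model(), n_mc = 500, seed = 1)
#' pb <- pbox(fam, "umf")
#' glance(pb)
#' @export
pbox <- function(family, pass = c("umf", "lmf")) {
  stopifnot(inherits(family, "cdf_family"))
  pass <- match.arg(pass)
  a0 <- min(attr(family, "alpha_levels"))
  sub <- dplyr::filter(tibble::as_tibble(family),
                       .data$pass == !!pass, .data$alpha == a0)
  if (nrow(sub) == 0) stop("family has no alpha = 0 member for this pass", call. = FALSE)
  structure(
    list(pass = pass, alpha = a0,
         minima = sub$min, maxima = sub$max,
         model = attr(family, "model"), n = nrow(sub)),
    class = "pbox"
  )
}

# analytic quantile of the minima/maxima curve at one (pass, alpha): pushes
# the single probabilistic parameter's analytic quantile through the corner
# evaluation; valid because the envelope is then a monotone function of that
# parameter
analytic_curve_quantile <- function(model, pass, alpha, curve, probs) {
  if (length(model$probabilistic) != 1) {
    stop("analytic quantile mode requires exactly one probabilistic parameter",
         call. = FALSE)
  }
  spec <- model$probabilistic[[1]]
  pname <- names(model$probabilistic)
  cuts <- cuts_at(model, alpha, pass)
  g <- function(q) {
    d <- stats::setNames(list(quantile(spec, q)), pname)
    env <- corner_envelope(model, d, cuts)
    if (curve == "min") env$min else env$max
  }
  increasing <- g(0.75) >= g(0.25)
  g(if (increasing) probs else 1 - probs)
}

# quantile of one bounding curve of a pbox, either convention
pbox_curve_quantile <- function(p, curve, probs,
                                mode = c("empirical", "analytic")) {
  mode <- match.arg(mode)
  if (mode == "empirical") {
    x <- if (curve == "min") p$minima else p$maxima
    quantile(ecdf_of(x), probs)
  } else {
    analytic_curve_quantile(p$model, p$pass, p$alpha, curve, probs)
  }
}

#' Interval-valued range of a p-box
#'
#' The range is reported between the `p_low` quantile of the minima curve and
#' the `p_high` quantile of the maxima curve. The defaults (0.5th and 99.5th
#' percentiles) are the convention under which the bounding curves' reported
#' endpoints are stable against single extreme draws; both are exposed.
#' `mode = "analytic"` replaces the empirical quantiles by the analytic
#' normal quantile pushed through the corner evaluation (deterministic; valid
#' for models with one probabilistic parameter in which the output is
#' monotone).
#'
#' @param p A [pbox()].
#' @param p_low,p_high Probabilities in `(0, 1)` with `p_low < p_high`.
#' @param mode `"empirical"` (from the Monte Carlo ECDFs) or `"analytic"`.
#' @return A [cut_interval()] `[lo, hi]`.
#' @export
pbox_range <- function(p, p_low = 0.005, p_high = 0.995,
                       mode = c("empirical", "analytic")) {
  stopifnot(inherits(p, "pbox"), p_low > 0, p_high < 1, p_low < p_high)
  mode <- match.arg(mode)
  cut_interval(pbox_curve_quantile(p, "min", p_low, mode),
               pbox_curve_quantile(p, "max", p_high, mode))
}

#' Interval-valued mean of a p-box
#'
#' The mean of every selection `x_i` in `[min_i, max_i]` lies between the
#' mean of the per-draw minima and the mean of the maxima; those two averages
#' are the sharp bounds.
#'
#' @param p A [pbox()].
#' @return A [cut_interval()].
#' @export
pbox_mean <- function(p) {
  stopifnot(inherits(p, "pbox"))
  cut_interval(mean(p$minima), mean(p$maxima))
}

#' Sharp bounds on the sample variance of interval data
#'
#' Given intervals `[lo_i, hi_i]`, bounds the variance of every selection
#' `x_i` in its interval. The lower bound is 0 exactly when all intervals
#' share a common point; otherwise the minimizing selection clamps each
#' interval to a common centre `m`, and the exact minimum is found by an
#' `O(n log n)` sweep over the candidate segments of `m` (within each
#' segment the clamped variance is quadratic in `m` with an interior
#' stationary point at the mean of the clamped values). The upper bound is
#' attained at interval endpoints, each `x_i` at the endpoint farther from
#' the selection mean; such selections are exactly the midpoint-threshold
#' selections (`hi_i` iff the interval midpoint exceeds the mean), so the
#' exact maximum is found by scanning the `n + 1` threshold selections in
#' midpoint order with prefix sums, again `O(n log n)`. Both bounds are
#' validated against full endpoint enumeration in the test-suite for small
#' `n`.
#'
#' @param lo,hi Numeric vectors of interval endpoints, `lo <= hi` elementwise.
#' @param divisor `"population"` (divide by `n`, the default) or `"sample"`
#'   (divide by `n - 1`).
#' @return A [cut_interval()] `[var_min, var_max]`.
#' @examples
#' interval_variance_bounds(c(0, 0), c(1, 1))   # [0, 0.25]
#' interval_variance_bounds(c(0, 1), c(0, 1))   # [0.25, 0.25]
#' @export
interval_variance_bounds <- function(lo, hi, divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  stopifnot(length(lo) == length(hi), all(is.finite(lo)), all(is.finite(hi)),
            all(lo <= hi))
  n <- length(lo)
  scale <- if (divisor == "population") n else n - 1
  if (n == 1) return(cut_interval(0, 0))
  pvar <- function(x) sum((x - mean(x))^2) / scale

  # ---- lower bound ----
  if (max(lo) <= min(hi)) {
    vmin <- 0 # all intervals share [max(lo), min(hi)]
  } else {
    # clamp to centre m; sweep segments between sorted endpoints, keeping
    # running sums of the values clamped at hi (m above hi_i) and at lo
    # (m below lo_i); free intervals contribute x_i = m
    brk <- sort(unique(c(lo, hi)))
    clamped_var <- function(m) {
      x <- pmin(pmax(m, lo), hi)
      pvar(x)
    }
    vmin <- Inf
    for (j in seq_len(length(brk) - 1L)) {
      l <- brk[j]; r <- brk[j + 1L]
      at_hi <- hi <= l          # clamped at hi throughout (l, r)
      at_lo <- lo >= r          # clamped at lo
      k <- n - sum(at_hi) - sum(at_lo)              # free count
      S <- sum(hi[at_hi]) + sum(lo[at_lo])          # clamped sum
      m_star <- if (k < n) S / (n - k) else l       # stationary point
      for (m in unique(pmin(pmax(m_star, l), r))) {
        vmin <- min(vmin, clamped_var(m))
      }
      vmin <- min(vmin, clamped_var(l), clamped_var(r))
    }
  }

  # ---- upper bound ----
  # at a maximizing selection every x_i sits at the endpoint farther from the
  # selection mean m, i.e. x_i = hi_i iff midpoint_i > m; so the optimum is
  # one of the n + 1 midpoint-threshold selections (lo for the k smallest
  # midpoints, hi for the rest), scanned with prefix sums
  ord <- order((lo + hi) / 2)
  lo_s <- lo[ord]; hi_s <- hi[ord]
  cs_lo <- cumsum(lo_s); cs_lo2 <- cumsum(lo_s^2)
  cs_hi <- rev(cumsum(rev(hi_s))); cs_hi2 <- rev(cumsum(rev(hi_s^2)))
  vmax <- -Inf
  for (k in 0:n) {
    S <- (if (k > 0) cs_lo[k] else 0) + (if (k < n) cs_hi[k + 1L] else 0)
    SS <- (if (k > 0) cs_lo2[k] else 0) + (if (k < n) cs_hi2[k + 1L] else 0)
    vmax <- max(vmax, (SS - S^2 / n) / scale)
  }

  cut_interval(max(vmin, 0), vmax)
}

#' Interval-valued variance of a p-box
#'
#' Sharp bounds of the sample variance over all selections `x_i` in the
#' per-draw interval `[min_i, max_i]`; see [interval_variance_bounds()].
#' The lower bound is 0 whenever all per-draw intervals share a common point,
#' which is typical for a p-box (the intervals all straddle the central
#' output region).
#'
#' @param p A [pbox()].
#' @param divisor Variance divisor convention; `"population"` (1/n, default)
#'   or `"sample"` (1/(n-1)).
#' @return A [cut_interval()].
#' @export
pbox_variance <- function(p, divisor = c("population", "sample")) {
  stopifnot(inherits(p, "pbox"))
  interval_variance_bounds(p$minima, p$maxima, divisor = match.arg(divisor))
}

#' @export
print.pbox <- function(x, ...) {
  rng <- pbox_range(x)
  mn <- pbox_mean(x)
  cat(sprintf("<pbox (%s pass, n = %d)>\n  range [%.6g, %.6g]  mean [%.6g, %.6g]\n",
              toupper(x$pass), x$n, rng[["lo"]], rng[["hi"]], mn[["lo"]], mn[["hi"]]))
  invisible(x)
}

#' Tidy a p-box into its bounding step curves
#'
#' @param x A [pbox()].
#' @param ... Unused.
#' @return A tibble with columns `curve` (`"min"`/`"max"`), `value`,
#'   `cumprob` — the two bounding ECDFs in step-coordinate form.
#' @export
tidy.pbox <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy.ecdf_t1(ecdf_of(x$minima)), curve = "min"),
    dplyr::mutate(tidy.ecdf_t1(ecdf_of(x$maxima)), curve = "max")
  )[, c("curve", "value", "cumprob")]
}

#' @rdname tidy.pbox
#' @param p_low,p_high Range percentiles, passed to [pbox_range()].
#' @param mode Quantile mode for the range, passed to [pbox_range()].
#' @return `glance()`: a one-row tibble with the pass, `n`, and the interval
#'   summaries `range_lo/hi`, `mean_lo/hi`, `var_lo/hi`.
#' @export
glance.pbox <- function(x, p_low = 0.005, p_high = 0.995,
                        mode = "empirical", ...) {
  rng <- pbox_range(x, p_low, p_high, mode = mode)
  mn <- pbox_mean(x)
  vr <- pbox_variance(x)
  tibble::tibble(
    pass = x$pass, n = x$n,
    range_lo = rng[["lo"]], range_hi = rng[["hi"]],
    mean_lo = mn[["lo"]], mean_hi = mn[["hi"]],
    var_lo = vr[["lo"]], var_hi = vr[["hi"]]
  )
}

#' Plot a probability box
#'
#' @param object A [pbox()].
#' @param ... Unused.
#' @return A ggplot object: the two bounding step CDFs.
#' @export
autoplot.pbox <- function(object, ...) {
  ggplot2::ggplot(tidy.pbox(object),
                  ggplot2::aes(.data$value, .data$cumprob, colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::labs(title = sprintf("p-box (%s pass)", toupper(object$pass)),
                  x = "model output", y = "cumulative probability") +
    ggplot2::theme_minimal()
}

#' Fractile membership function of the model output
#'
#' At a fixed cumulative probability `p`, each (pass, alpha) member of the
#' family contributes the quantile interval
#' `[Q_p(minima ECDF), Q_p(maxima ECDF)]`. By alpha-cut nesting these
#' intervals nest as alpha grows, so the alpha = 0 interval gives the support
#' and the alpha = w interval the core of a trapezoidal generalized fuzzy
#' number of height w; the UMF pass yields the upper membership function and
#' the LMF pass the lower one. The result is a completely generalized
#' interval-valued fuzzy number of the output at fractile `p` (its height w
#' is below 1 whenever a generalized fuzzy input is present).
#'
#' @param family A `"cdf_family"` from [propagate()].
#' @param p Fractile in `(0, 1)` (e.g. 0.95 for the 95th fractile).
#' @param mode `"empirical"` quantiles from the Monte Carlo ECDFs, or
#'   `"analytic"` (deterministic; single probabilistic parameter).
#' @return An object of class `"fractile_mf"`: the fractile `p`, height `w`,
#'   `umf` and `lmf` as [gfn()] objects, and the full per-alpha quantile
#'   table (`alpha_table`).
#' @examples
#' fam <- propagate(arsenic_model(), n_mc = 500, seed = 1)
#' fractile_mf(fam, 0.95, mode = "analytic")
#' @export
fractile_mf <- function(family, p, mode = c("empirical", "analytic")) {
  stopifnot(inherits(family, "cdf_family"), p > 0, p < 1)
  mode <- match.arg(mode)
  levels <- attr(family, "alpha_levels")
  w <- attr(family, "w")
  model <- attr(family, "model")
  fam <- tibble::as_tibble(family)

  qrow <- function(pass, alpha) {
    if (mode == "empirical") {
      sub <- dplyr::filter(fam, .data$pass == !!pass, .data$alpha == !!alpha)
      c(lo = quantile(ecdf_of(sub$min), p), hi = quantile(ecdf_of(sub$max), p))
    } else {
      c(lo = analytic_curve_quantile(model, pass, alpha, "min", p),
        hi = analytic_curve_quantile(model, pass, alpha, "max", p))
    }
  }
  tab <- tidyr::expand_grid(pass = c("umf", "lmf"), alpha = levels)
  qs <- purrr::pmap(tab, function(pass, alpha) qrow(pass, alpha))
  tab$lo <- vapply(qs, `[[`, numeric(1), "lo")
  tab$hi <- vapply(qs, `[[`, numeric(1), "hi")

  h_out <- if (w > 0) w else 1 # degenerate pure-MC family: crisp, full height
  mf_of <- function(pass) {
    supp <- dplyr::filter(tab, .data$pass == !!pass, .data$alpha == min(levels))
    core <- dplyr::filter(tab, .data$pass == !!pass, .data$alpha == max(levels))
    gfn(supp$lo, core$lo, core$hi, supp$hi, height = h_out)
  }
  structure(
    list(p = p, height = w, umf = mf_of("umf"), lmf = mf_of("lmf"),
         alpha_table = tab, mode = mode),
    class = "fractile_mf"
  )
}

#' @export
print.fractile_mf <- function(x, ...) {
  cat(sprintf("<fractile_mf at p = %g (height %g, %s quantiles)>\n  umf: %s\n  lmf: %s\n",
              x$p, x$height, x$mode, format(x$umf), format(x$lmf)))
  invisible(x)
}

#' Tidy a fractile membership function
#'
#' @param x A `"fractile_mf"`.
#' @param ... Unused.
#' @return The per-alpha quantile-interval table: columns `pass`, `alpha`,
#'   `lo`, `hi`.
#' @export
tidy.fractile_mf <- function(x, ...) x$alpha_table

#' @rdname tidy.fractile_mf
#' @return `glance()`: a one-row tibble with `p`, `height` and the eight
#'   trapezoid knots `umf_a` ... `lmf_d`.
#' @export
glance.fractile_mf <- function(x, ...) {
  tibble::tibble(
    p = x$p, height = x$height,
    umf_a = x$umf$a, umf_b = x$umf$b, umf_c = x$umf$c, umf_d = x$umf$d,
    lmf_a = x$lmf$a, lmf_b = x$lmf$b, lmf_c = x$lmf$c, lmf_d = x$lmf$d
  )
}

#' Plot a fractile membership function
#'
#' @param object A `"fractile_mf"`.
#' @param ... Unused.
#' @return A ggplot object: the trapezoidal upper and lower membership
#'   functions of the output at the fractile.
#' @export
autoplot.fractile_mf <- function(object, ...) {
  poly <- function(g, mf) {
    tibble::tibble(mf = mf,
                   x = c(g$a, g$b, g$c, g$d),
                   mu = c(0, g$w, g$w, 0))
  }
  df <- dplyr::bind_rows(poly(object$umf, "umf"), poly(object$lmf, "lmf"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$mu, colour = .data$mf)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = sprintf("output membership at fractile p = %g", object$p),
                  x = "model output", y = "membership degree") +
    ggplot2::theme_minimal()
}
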