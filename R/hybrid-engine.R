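# Two-pass alpha-swept corner evaluation of a model over Monte Carlo samples.
#
# The model M = (P_i, G_k, F_l) mixes probabilistic parameters P_i (sampled
# once by inverse transform), generalized fuzzy numbers G_k, and normal
# interval-valued fuzzy numbers F_l. For each membership level alpha on an
# 11-point grid 0..w (w = smallest GFN height) the fuzzy parameters are
# replaced by their alpha-cut intervals and the model is evaluated at every
# corner of the resulting box (vertex method), per Monte Carlo draw. The
# per-draw extrema give one minima and one maxima empirical CDF per (pass,
# alpha); the UMF pass uses each IVFN's upper membership function and the LMF
# pass its lower one, with GFNs treated identically in both passes.

#' Declare a hybrid uncertainty model
#'
#' Partitions named parameters into constants (bare numerics), probabilistic
#' parameters ([dist_normal()] specs), generalized fuzzy numbers ([gfn()])
#' and interval-valued fuzzy numbers ([ivfn()]), and attaches the evaluator
#' that maps one full parameter assignment to one model output.
#'
#' @param evaluator A function whose formal arguments are exactly the
#'   parameter names (in any order). It must be vectorized over its
#'   probabilistic arguments (plain arithmetic is) and return finite values
#'   on the declared domains.
#' @param params Named list; each element a bare numeric (constant), a
#'   `"dist_spec"`, a `"gfn"`, or an `"ivfn"`.
#' @param name Optional model label, carried into exports.
#' @return An object of class `"hybrid_model"`.
#' @examples
#' m <- hybrid_model(
#'   function(x, y, z) x * y / z,
#'   params = list(x = gfn(4, 5, 6, height = 0.8),
#'                 y = ivfn(gfn(35, 45, 55), gfn(40, 45, 50)),
#'                 z = dist_normal(70, 5))
#' )
#' @export
hybrid_model <- function(evaluator, params, name = NULL) {
  stopifnot(is.function(evaluator), is.list(params), length(params) >= 1)
  nm <- names(params)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("params must be uniquely named", call. = FALSE)
  }
  kind <- vapply(params, function(p) {
    if (inherits(p, "gfn")) "gfn"
    else if (inherits(p, "ivfn")) "ivfn"
    else if (inherits(p, "dist_spec")) {
      if (p$family == "constant") "constant" else "probabilistic"
    }
    else if (is.numeric(p) && length(p) == 1 && is.finite(p)) "constant"
    else "invalid"
  }, character(1))
  if (any(kind == "invalid")) {
    stop("unsupported parameter type for: ",
         paste(nm[kind == "invalid"], collapse = ", "), call. = FALSE)
  }
  fml <- names(formals(evaluator))
  if (!("..." %in% fml)) {
    missing <- setdiff(nm, fml)
    unused <- setdiff(fml, nm)
    if (length(missing) || length(unused)) {
      stop("evaluator arguments must match parameter names; missing: ",
           paste(missing, collapse = ", "), "; unused: ",
           paste(unused, collapse = ", "), call. = FALSE)
    }
  }
  constants <- lapply(params[kind == "constant"],
                      function(p) if (inherits(p, "dist_spec")) p$value else p)
  structure(
    list(evaluator = evaluator,
         params = params,
         kind = kind,
         constants = constants,
         probabilistic = params[kind == "probabilistic"],
         gfns = params[kind == "gfn"],
         ivfns = params[kind == "ivfn"],
         name = name %||% "model"),
    class = "hybrid_model"
  )
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("<hybrid_model '%s': %d constant, %d probabilistic, %d GFN, %d IVFN>\n",
              x$name, length(x$constants), length(x$probabilistic),
              length(x$gfns), length(x$ivfns)))
  invisible(x)
}

#' Tidy a hybrid model into its parameter table
#'
#' @param x A [hybrid_model()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `parameter`, `kind`, and a
#'   compact `description`.
#' @export
tidy.hybrid_model <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$params),
    kind = unname(x$kind),
    description = vapply(x$params, function(p) {
      if (inherits(p, "gfn") || inherits(p, "ivfn")) format(p)
      else if (inherits(p, "dist_spec") && p$family == "normal")
        sprintf("Normal(%g, %g)", p$mean, p$sd)
      else if (inherits(p, "dist_spec")) sprintf("%g", p$value)
      else sprintf("%g", p)
    }, character(1))
  )
}

#' Membership-level grid for the alpha sweep
#'
#' The sweep runs over 11 equally spaced membership levels from 0 to
#' `w = min(w_s, 1)`, the smallest height among the model's generalized fuzzy
#' numbers (IVFNs entering the engine are normal, height 1, so they do not
#' lower `w`). Both endpoints are evaluated. With no fuzzy parameters the
#' model degenerates to pure Monte Carlo and the grid collapses to `{0}`,
#' with a warning.
#'
#' @param model A [hybrid_model()].
#' @param alpha_steps Number of steps (default 10, giving 11 levels at
#'   spacing `w / alpha_steps`).
#' @return A list with elements `w` and `levels`.
#' @examples
#' m <- hybrid_model(function(x) x, list(x = gfn(4, 5, 6, height = 0.8)))
#' make_alpha_grid(m)$levels   # 0, 0.08, ..., 0.8
#' @export
make_alpha_grid <- function(model, alpha_steps = 10) {
  stopifnot(inherits(model, "hybrid_model"), alpha_steps >= 1)
  heights <- c(vapply(model$gfns, fuzzy_height, numeric(1)),
               vapply(model$ivfns, fuzzy_height, numeric(1)))
  if (length(heights) == 0) {
    warning("model has no fuzzy parameters; alpha grid degenerates to {0} (pure Monte Carlo)",
            call. = FALSE)
    return(list(w = 0, levels = 0))
  }
  w <- min(heights, 1)
  list(w = w, levels = seq(0, w, length.out = alpha_steps + 1))
}

# alpha-cuts for every fuzzy parameter of a model at one level, for one pass
cuts_at <- function(model, alpha, pass) {
  cuts <- c(
    lapply(model$gfns, alpha_cut, alpha = alpha),
    lapply(model$ivfns, function(f) {
      alpha_cut(if (pass == "umf") f$umf else f$lmf, alpha)
    })
  )
  cuts
}

#' Extrema of a model over the corners of its fuzzy-cut box
#'
#' The vertex method: with the probabilistic draw held fixed, the model is
#' evaluated at every combination of interval endpoints of the fuzzy
#' parameters' alpha-cuts (2^k corners for k fuzzy parameters) and the
#' minimum and maximum are returned. Exact for models monotone in each fuzzy
#' argument; for non-monotone models an interior extremum can be missed, and
#' `grid_points > 2` replaces the corners by a dense lattice per cut as a
#' refinement.
#'
#' @param model A [hybrid_model()].
#' @param draw Named list or vector of values for the probabilistic
#'   parameters; each may be a vector of Monte Carlo draws (the evaluator is
#'   applied vectorized).
#' @param cuts Named list of non-empty [cut_interval()]s, one per fuzzy
#'   parameter.
#' @param grid_points Evaluation points per cut dimension; 2 (the default) is
#'   the vertex method proper.
#' @return A list with numeric `min` and `max`, each the length of the draw.
#' @examples
#' m <- hybrid_model(function(x, y) x + y,
#'                   list(x = gfn(0, 0.5, 1), y = gfn(2, 2.5, 3)))
#' corner_envelope(m, draw = list(),
#'                 cuts = list(x = cut_interval(0, 1), y = cut_interval(2, 3)))
#' @export
corner_envelope <- function(model, draw, cuts, grid_points = 2) {
  stopifnot(inherits(model, "hybrid_model"), grid_points >= 2)
  fuzzy_names <- c(names(model$gfns), names(model$ivfns))
  stopifnot(setequal(names(cuts), fuzzy_names))
  if (any(vapply(cuts, is_empty_cut, logical(1)))) {
    stop("empty alpha-cut supplied to corner evaluation", call. = FALSE)
  }
  pts <- lapply(cuts, function(ci) {
    if (grid_points == 2) c(ci[["lo"]], ci[["hi"]])
    else seq(ci[["lo"]], ci[["hi"]], length.out = grid_points)
  })
  corners <- expand.grid(pts, KEEP.OUT.ATTRS = FALSE)
  n_draw <- if (length(draw)) length(draw[[1]]) else 1L
  lo <- rep(Inf, n_draw)
  hi <- rep(-Inf, n_draw)
  base_args <- c(model$constants, as.list(draw))
  for (j in seq_len(nrow(corners))) {
    out <- do.call(model$evaluator, c(base_args, as.list(corners[j, , drop = FALSE])))
    if (!all(is.finite(out))) {
      stop("model evaluator returned non-finite output at a corner", call. = FALSE)
    }
    lo <- pmin(lo, out)
    hi <- pmax(hi, out)
  }
  list(min = lo, max = hi)
}

#' Propagate variability and fuzzy uncertainty through a model
#'
#' Runs the full two-pass alpha sweep: one uniform stream per probabilistic
#' parameter is drawn once (inverse-transform sampling) and reused across all
#' membership levels and both passes, so the per-draw intervals nest exactly
#' as alpha increases. Pass `"umf"` uses each IVFN's upper membership
#' function, pass `"lmf"` its lower; generalized fuzzy numbers are used
#' identically in both. For each (pass, alpha) the per-draw corner extrema
#' form one minima and one maxima empirical CDF; the collection over the grid
#' is the family of CDFs from which probability boxes ([pbox()]) and fractile
#' membership functions ([fractile_mf()]) are read.
#'
#' IVFN parameters must be normal (both heights 1); generalized IVFNs are
#' rejected, as the method is undefined for them.
#'
#' @param model A [hybrid_model()].
#' @param n_mc Number of Monte Carlo draws (default 5000).
#' @param seed Integer seed (required; the run is reproducible from it).
#' @param alpha_steps Steps of the alpha grid (default 10, i.e. 11 levels).
#' @param refine_nonmonotone If `TRUE`, corner evaluation is refined with a
#'   dense lattice per cut (`grid_points` points) to guard against
#'   non-monotone evaluators; default `FALSE` (pure vertex method).
#' @param grid_points Lattice size per cut when refining; default 20.
#' @return A tibble of class `"cdf_family"` with columns `pass`, `alpha`,
#'   `draw`, `min`, `max`; one row per (pass, alpha level, Monte Carlo draw).
#'   The model, seed, alpha grid and sampled probabilistic draws are attached
#'   as attributes for downstream summaries.
#' @examples
#' fam <- propagate(arsenic_model(), n_mc = 200, seed = 1)
#' dplyr::count(fam, pass, alpha)
#' @export
propagate <- function(model, n_mc = 5000, seed, alpha_steps = 10,
                      refine_nonmonotone = FALSE, grid_points = 20) {
  stopifnot(inherits(model, "hybrid_model"), n_mc >= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  for (nm in names(model$ivfns)) {
    viol <- validate_fuzzy(model$ivfns[[nm]], context = "engine")
    if (length(viol)) {
      stop(sprintf("parameter '%s': %s", nm, paste(viol, collapse = "; ")),
           call. = FALSE)
    }
  }
  grid <- make_alpha_grid(model, alpha_steps)

  # one uniform stream per probabilistic parameter, drawn once before the
  # alpha loop and shared by every level and both passes
  set.seed(as.integer(seed))
  prob_names <- names(model$probabilistic)
  draws <- lapply(model$probabilistic, function(spec) {
    quantile(spec, stats::runif(n_mc))
  })
  n_draw <- if (length(draws)) n_mc else 1L
  gp <- if (refine_nonmonotone) grid_points else 2

  has_fuzzy <- length(model$gfns) + length(model$ivfns) > 0
  rows <- list()
  for (pass in c("umf", "lmf")) {
    for (alpha in grid$levels) {
      env <- if (has_fuzzy) {
        corner_envelope(model, draws, cuts_at(model, alpha, pass), grid_points = gp)
      } else {
        out <- do.call(model$evaluator, c(model$constants, draws))
        if (!all(is.finite(out))) stop("model evaluator returned non-finite output", call. = FALSE)
        list(min = out, max = out)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pass = pass, alpha = alpha, draw = seq_len(n_draw),
        min = env$min, max = env$max
      )
    }
  }
  fam <- dplyr::bind_rows(rows)
  structure(
    fam,
    class = c("cdf_family", class(fam)),
    model = model, seed = as.integer(seed), n_mc = n_draw,
    w = grid$w, alpha_levels = grid$levels, samples = draws,
    refined = refine_nonmonotone
  )
}

#' Tidy a CDF family into long curve format
#'
#' @param x A `"cdf_family"` from [propagate()].
#' @param ... Unused.
#' @return A tibble with columns `pass`, `alpha`, `curve` (`"min"`/`"max"`),
#'   `draw`, `value` — the long export format.
#' @export
tidy.cdf_family <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), c("min", "max"),
                      names_to = "curve", values_to = "value")
}

#' @rdname tidy.cdf_family
#' @return `glance()`: a one-row tibble with `n_mc`, `n_alpha`, `w`, `seed`,
#'   and the model name.
#' @export
glance.cdf_family <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model")$name,
    n_mc = attr(x, "n_mc"),
    n_alpha = length(attr(x, "alpha_levels")),
    w = attr(x, "w"),
    seed = attr(x, "seed")
  )
}

#' @export
print.cdf_family <- function(x, ...) {
  g <- glance.cdf_family(x)
  cat(sprintf("<cdf_family of '%s': 2 passes x %d alpha levels (w = %g), %d MC draws, seed %d>\n",
              g$model, g$n_alpha, g$w, g$n_mc, g$seed))
  NextMethod()
}

#' Plot a family of CDFs
#'
#' Step curves of the per-draw minima and maxima ECDFs, colored by membership
#' level and faceted by pass; alpha = 0 gives the outermost (p-box) pair.
#'
#' @param object A `"cdf_family"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdf_family <- function(object, ...) {
  long <- tidy.cdf_family(object)
  long <- dplyr::arrange(dplyr::group_by(long, .data$pass, .data$alpha, .data$curve),
                         .data$value)
  long <- dplyr::mutate(long, cumprob = dplyr::row_number() / dplyr::n())
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$cumprob,
                                     group = interaction(.data$alpha, .data$curve),
                                     colour = .data$alpha)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~pass) +
    ggplot2::labs(x = "model output", y = "cumulative probability",
                  colour = expression(alpha)) +
    ggplot2::theme_minimal()
}
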