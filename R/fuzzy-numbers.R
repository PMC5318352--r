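# Generalized fuzzy numbers and interval-valued fuzzy numbers.
#
# A generalized fuzzy number (GFN) is a trapezoidal possibility distribution
# with knots a <= b <= c <= d and height w in (0, 1]: membership is 0 at a and
# d, w on the core [b, c], and linear on the legs. Triangular numbers are the
# special case b == c. An interval-valued fuzzy number (IVFN) bounds the
# membership degree at each point by a pair of GFNs (upper and lower
# membership functions).

#' Create a generalized fuzzy number
#'
#' A generalized fuzzy number (GFN) is a trapezoidal possibility distribution
#' `[a, b, c, d; w]`: membership rises linearly from 0 at `a` to the height
#' `w` at `b`, stays at `w` on the core `[b, c]`, and falls linearly back to 0
#' at `d`. Heights below 1 encode partial confidence in the possibility
#' distribution itself. Triangular numbers `[a, m, d; w]` are entered by
#' omitting `d` (the core collapses to the single point `m`), and a crisp
#' constant by `gfn(x, x, x, x)`.
#'
#' @param a,b,c,d Real knots with `a <= b <= c <= d`, in the units of the
#'   quantity being described. When `d` is omitted the input is read as the
#'   triangular number `[a, b, c; height]` and normalized to the trapezoid
#'   `(a, b, b, c)`.
#' @param height Maximum membership degree `w`, in `(0, 1]`. Default 1
#'   (a normal fuzzy number).
#' @return An object of class `"gfn"`.
#' @examples
#' gfn(4, 5, 6, height = 0.8)        # triangular [4,5,6; 0.8]
#' gfn(35, 40, 50, 55)               # trapezoidal, height 1
#' @seealso [ivfn()], [alpha_cut()], [membership()]
#' @export
gfn <- function(a, b, c, d = NULL, height = 1) {
  if (is.null(d)) { # triangular [a, m, d; w] -> trapezoid (a, m, m, d)
    d <- c
    c <- b
  }
  g <- structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         d = as.numeric(d), w = as.numeric(height)),
    class = "gfn"
  )
  viol <- validate_fuzzy(g)
  if (length(viol)) {
    stop("invalid generalized fuzzy number: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  g
}

#' Create an interval-valued fuzzy number
#'
#' An interval-valued fuzzy number (IVFN) assigns each point an interval of
#' membership degrees, bounded below by a lower membership function (LMF) and
#' above by an upper membership function (UMF), both generalized fuzzy
#' numbers. The LMF must sit inside the UMF: at every membership level up to
#' the LMF's height, the LMF alpha-cut is contained in the UMF alpha-cut. An
#' IVFN is *normal* when both heights equal 1 and *completely generalized*
#' when both are below 1; the propagation engine accepts normal IVFNs only.
#'
#' @param umf,lmf Upper and lower membership functions, as [gfn()] objects.
#' @return An object of class `"ivfn"`.
#' @examples
#' ivfn(umf = gfn(35, 45, 55), lmf = gfn(40, 45, 50))
#' @export
ivfn <- function(umf, lmf) {
  f <- structure(list(umf = umf, lmf = lmf), class = "ivfn")
  viol <- validate_fuzzy(f)
  if (length(viol)) {
    stop("invalid interval-valued fuzzy number: ",
         paste(viol, collapse = "; "), call. = FALSE)
  }
  f
}

#' Closed interval returned by an alpha-cut
#'
#' @param lo,hi Interval endpoints, `lo <= hi`.
#' @return A length-2 numeric of class `"cut_interval"`, or the distinguished
#'   empty cut from `empty_cut()`.
#' @export
cut_interval <- function(lo, hi) {
  stopifnot(is.finite(lo), is.finite(hi), lo <= hi)
  structure(c(lo = lo, hi = hi), class = "cut_interval")
}

#' @rdname cut_interval
#' @export
empty_cut <- function() {
  structure(numeric(0), class = c("empty_cut", "cut_interval"))
}

#' @rdname cut_interval
#' @param x Object to test.
#' @export
is_empty_cut <- function(x) inherits(x, "empty_cut")

#' Alpha-cut of a fuzzy number
#'
#' The alpha-cut of a fuzzy set is the crisp set of points whose membership
#' degree is at least `alpha`. For a trapezoidal GFN of height `w` this is the
#' closed interval `[a + (b - a) * alpha / w, d - (d - c) * alpha / w]` when
#' `alpha <= w`, and the empty set when `alpha > w`. For an IVFN the cut is a
#' pair of intervals, one per bounding membership function, with three cases:
#' both cuts exist when `alpha` is at most the LMF height; only the UMF cut
#' exists when `alpha` lies between the two heights; neither exists above the
#' UMF height.
#'
#' @param x A [gfn()] or [ivfn()] object.
#' @param alpha Membership level in `[0, 1]`.
#' @param ... Unused; for method consistency.
#' @return For a GFN, a [cut_interval()] (possibly empty). For an IVFN, a list
#'   of class `"ivfn_cut"` with elements `lmf` and `umf`, each a
#'   [cut_interval()] (possibly empty).
#' @examples
#' alpha_cut(gfn(4, 5, 6, height = 0.8), 0.4)   # [4.5, 5.5]
#' alpha_cut(gfn(4, 5, 6, height = 0.8), 0.9)   # empty
#' alpha_cut(ivfn(gfn(35, 45, 55), gfn(40, 45, 50)), 0.5)
#' @export
alpha_cut <- function(x, alpha, ...) UseMethod("alpha_cut")

#' @rdname alpha_cut
#' @export
alpha_cut.gfn <- function(x, alpha, ...) {
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha >= 0, alpha <= 1)
  if (alpha > x$w) return(empty_cut())
  cut_interval(x$a + (x$b - x$a) * alpha / x$w,
               x$d - (x$d - x$c) * alpha / x$w)
}

#' @rdname alpha_cut
#' @export
alpha_cut.ivfn <- function(x, alpha, ...) {
  structure(
    list(lmf = alpha_cut(x$lmf, alpha), umf = alpha_cut(x$umf, alpha)),
    class = "ivfn_cut"
  )
}

#' Membership degree of a point in a generalized fuzzy number
#'
#' Piecewise-linear membership: 0 outside the support `[a, d]`, the height `w`
#' on the core `[b, c]`, linear interpolation on the legs. Zero-width legs
#' (`a == b` or `c == d`) take the limit convention: membership jumps to `w`
#' at the knot, which keeps [alpha_cut()] total and inverse-consistent.
#'
#' @param g A [gfn()] object.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of membership degrees in `[0, w]`.
#' @examples
#' membership(gfn(4, 5, 6, height = 0.8), c(4.5, 5, 7))  # 0.4, 0.8, 0
#' @export
membership <- function(g, x) {
  stopifnot(inherits(g, "gfn"))
  mu <- numeric(length(x))
  inside <- x >= g$a & x <= g$d
  core <- x >= g$b & x <= g$c
  left <- inside & x < g$b
  right <- inside & x > g$c
  mu[core] <- g$w
  # zero-width legs leave no strictly-interior points, so the jump-to-w
  # convention is realised by the core assignment above
  if (g$b > g$a) mu[left] <- g$w * (x[left] - g$a) / (g$b - g$a)
  if (g$d > g$c) mu[right] <- g$w * (g$d - x[right]) / (g$d - g$c)
  mu
}

#' Height and support of a fuzzy number
#'
#' The height is the largest membership degree attained; the support is the
#' closure of the set of points with positive membership, here the interval
#' `[a, d]`.
#'
#' @param x A [gfn()] or [ivfn()] object.
#' @return `fuzzy_height()`: a scalar in `(0, 1]` (for an IVFN, the UMF
#'   height). `fuzzy_support()`: a [cut_interval()].
#' @export
fuzzy_height <- function(x) {
  if (inherits(x, "ivfn")) x$umf$w else x$w
}

#' @rdname fuzzy_height
#' @export
fuzzy_support <- function(x) {
  if (inherits(x, "ivfn")) x <- x$umf
  cut_interval(x$a, x$d)
}

#' Validate a fuzzy number and list every violated invariant
#'
#' Checks knot ordering, height bounds and finiteness for a GFN; for an IVFN
#' additionally the height ordering and the nesting of the lower membership
#' function inside the upper one. With `context = "engine"` an IVFN must be
#' normal (both heights exactly 1): the propagation method is undefined for
#' generalized IVFN inputs and they are rejected with the distinct violation
#' `"generalized IVFN unsupported"`.
#'
#' @param x A [gfn()] or [ivfn()] object (or a bare list with the same
#'   fields, so malformed candidates can be checked).
#' @param context `"standalone"` (default) checks the type invariants only;
#'   `"engine"` applies the engine-entry restriction on IVFN heights.
#' @return A character vector of violations; `character(0)` means valid.
#' @examples
#' validate_fuzzy(gfn(4, 5, 6, height = 0.8))                 # character(0)
#' validate_fuzzy(structure(list(a = 6, b = 5, c = 5, d = 4, w = 1),
#'                          class = "gfn"))
#' @export
validate_fuzzy <- function(x, context = c("standalone", "engine")) {
  context <- match.arg(context)
  if (inherits(x, "ivfn") || (is.list(x) && !is.null(x$umf) && !is.null(x$lmf))) {
    viol <- character(0)
    viol <- c(viol, validate_fuzzy(x$umf), validate_fuzzy(x$lmf))
    if (length(viol)) return(paste0("ivfn: ", viol))
    if (x$lmf$w > x$umf$w) {
      viol <- c(viol, "LMF height exceeds UMF height")
    } else {
      # linear legs: containment at alpha = 0 and alpha = h(lmf) implies
      # containment at every alpha in between
      for (a in c(0, x$lmf$w)) {
        cu <- alpha_cut.gfn(x$umf, a)
        cl <- alpha_cut.gfn(x$lmf, a)
        if (cl[["lo"]] < cu[["lo"]] - 1e-9 * max(1, abs(cu[["lo"]])) ||
            cl[["hi"]] > cu[["hi"]] + 1e-9 * max(1, abs(cu[["hi"]]))) {
          viol <- c(viol, sprintf("LMF alpha-cut not nested in UMF alpha-cut at alpha = %g", a))
        }
      }
    }
    if (context == "engine" && (x$umf$w != 1 || x$lmf$w != 1)) {
      viol <- c(viol, "generalized IVFN unsupported")
    }
    return(viol)
  }
  viol <- character(0)
  knots <- c(x$a, x$b, x$c, x$d)
  if (!all(is.finite(knots))) viol <- c(viol, "knots not finite")
  else if (is.unsorted(knots)) viol <- c(viol, "knots not sorted")
  if (!is.finite(x$w) || x$w <= 0 || x$w > 1) viol <- c(viol, "height not in (0, 1]")
  viol
}

#' @export
format.gfn <- function(x, ...) {
  if (x$b == x$c) {
    sprintf("<gfn tri [%g, %g, %g; %g]>", x$a, x$b, x$d, x$w)
  } else {
    sprintf("<gfn trap [%g, %g, %g, %g; %g]>", x$a, x$b, x$c, x$d, x$w)
  }
}

#' @export
print.gfn <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.ivfn <- function(x, ...) {
  sprintf("<ivfn umf = %s, lmf = %s>", format(x$umf), format(x$lmf))
}

#' @export
print.ivfn <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.cut_interval <- function(x, ...) {
  if (is_empty_cut(x)) cat("<empty cut>\n")
  else cat(sprintf("[%g, %g]\n", x[["lo"]], x[["hi"]]))
  invisible(x)
}

#' @export
print.ivfn_cut <- function(x, ...) {
  cat("ivfn cut:\n  lmf: ")
  print(x$lmf)
  cat("  umf: ")
  print(x$umf)
  invisible(x)
}

#' Tidy a fuzzy number into a one-row tibble of knots
#'
#' @param x A [gfn()] or [ivfn()] object.
#' @param ... Unused.
#' @return A tibble with one row per membership function (`mf` is `"mf"` for
#'   a plain GFN, `"umf"`/`"lmf"` for an IVFN) and columns `a`, `b`, `c`,
#'   `d`, `height`.
#' @export
tidy.gfn <- function(x, ...) {
  tibble::tibble(mf = "mf", a = x$a, b = x$b, c = x$c, d = x$d, height = x$w)
}

#' @rdname tidy.gfn
#' @export
tidy.ivfn <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy.gfn(x$umf), mf = "umf"),
    dplyr::mutate(tidy.gfn(x$lmf), mf = "lmf")
  )
}
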