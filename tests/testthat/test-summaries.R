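# fabricate a minimal pbox from raw per-draw intervals
pbox_from <- function(lo, hi, pass = "umf") {
  structure(list(pass = pass, alpha = 0, minima = lo, maxima = hi,
                 model = NULL, n = length(lo)),
            class = "pbox")
}

test_that("the p-box is the alpha = 0 envelope of its pass", {
  fam <- arsenic_family(n_mc = 400, seed = 8)
  pb <- pbox(fam, "umf")
  expect_equal(pb$n, 400)
  expect_true(all(pb$minima <= pb$maxima))
  # the alpha = 0 curves envelope the alpha = w curves pointwise
  top <- fam[fam$pass == "umf" & fam$alpha == attr(fam, "w"), ]
  Fmin0 <- ecdf_of(pb$minima); Fmin8 <- ecdf_of(top$min)
  Fmax0 <- ecdf_of(pb$maxima); Fmax8 <- ecdf_of(top$max)
  grid <- seq(min(pb$minima), max(pb$maxima), length.out = 500)
  expect_true(all(Fmin0(grid) >= Fmin8(grid) - 1e-12)) # left bound dominates
  expect_true(all(Fmax0(grid) <= Fmax8(grid) + 1e-12)) # right bound is dominated
})

test_that("p-box range and mean follow their interval conventions", {
  # constant model: zero-width summaries
  cpb <- pbox_from(rep(2, 10), rep(2, 10))
  expect_equal(unclass(pbox_range(cpb)), c(lo = 2, hi = 2))
  expect_equal(unclass(pbox_mean(cpb)), c(lo = 2, hi = 2))

  # endpoint averages
  expect_equal(unclass(pbox_mean(pbox_from(c(0, 2), c(1, 3)))), c(lo = 1, hi = 2))

  # range widens monotonically as the percentiles widen
  fam <- arsenic_family(n_mc = 400, seed = 8)
  pb <- pbox(fam, "umf")
  r1 <- pbox_range(pb, 0.05, 0.95)
  r2 <- pbox_range(pb, 0.005, 0.995)
  expect_lte(r2[["lo"]], r1[["lo"]])
  expect_gte(r2[["hi"]], r1[["hi"]])
  # and stays inside the sample extremes of the alpha = 0 envelope
  expect_gte(r2[["lo"]], min(pb$minima))
  expect_lte(r2[["hi"]], max(pb$maxima))
  expect_error(pbox_range(pb, 0.9, 0.1))
})

test_that("interval variance bounds are sharp on small enumerable cases", {
  expect_equal(unclass(interval_variance_bounds(c(0, 0), c(1, 1))),
               c(lo = 0, hi = 0.25))
  expect_equal(unclass(interval_variance_bounds(c(0, 1), c(0, 1))),
               c(lo = 0.25, hi = 0.25))
  # disjoint intervals force spread
  v <- interval_variance_bounds(c(0, 5), c(1, 6))
  expect_gt(v[["lo"]], 0)
  expect_equal(v[["hi"]], max(enumerate_selection_vars(c(0, 5), c(1, 6))))
  # lower bound at the closest approach of the two intervals: x = (1, 5)
  expect_equal(v[["lo"]], mean((c(1, 5) - 3)^2))

  # sample divisor convention
  vs <- interval_variance_bounds(c(0, 0), c(1, 1), divisor = "sample")
  expect_equal(vs[["hi"]], 0.5)
})

test_that("variance bounds bracket every endpoint selection and detect common points", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    lo <- runif(n, -5, 5)
    hi <- lo + rexp(n, rate = if (i %% 2) 2 else 0.2)
    v <- interval_variance_bounds(lo, hi)
    vars <- enumerate_selection_vars(lo, hi)
    expect_lte(v[["lo"]], min(vars) + 1e-12)
    expect_gte(v[["hi"]], max(vars) - 1e-12)
    # the upper bound is attained by some endpoint selection
    expect_equal(v[["hi"]], max(vars), tolerance = 1e-9)
    # zero lower bound exactly when the intervals share a common point
    expect_equal(v[["lo"]] == 0, max(lo) <= min(hi))
    # interior selections too
    for (j in 1:20) {
      x <- runif(n, lo, hi)
      pv <- mean((x - mean(x))^2)
      expect_true(pv >= v[["lo"]] - 1e-12 && pv <= v[["hi"]] + 1e-12)
    }
  }
})

test_that("fractile membership functions nest, grow with p, and keep the alpha table", {
  fam <- arsenic_family(n_mc = 2000, seed = 12)
  mf95 <- fractile_mf(fam, 0.95)
  mf85 <- fractile_mf(fam, 0.85)
  expect_equal(mf95$height, 0.8)
  expect_equal(mf95$umf$w, 0.8)
  # LMF nested inside UMF
  expect_lte(mf95$umf$a, mf95$lmf$a)
  expect_gte(mf95$umf$d, mf95$lmf$d)
  # monotone in p, knot by knot
  k95 <- unlist(glance(mf95)[, c("umf_a", "umf_b", "umf_c", "umf_d")])
  k85 <- unlist(glance(mf85)[, c("umf_a", "umf_b", "umf_c", "umf_d")])
  expect_true(all(k95 >= k85))
  # per-alpha intervals nest as alpha increases
  tab <- dplyr::arrange(tidy(mf95), pass, alpha)
  for (pp in c("umf", "lmf")) {
    sub <- tab[tab$pass == pp, ]
    expect_true(all(diff(sub$lo) >= -1e-15))
    expect_true(all(diff(sub$hi) <= 1e-15))
  }
  expect_error(fractile_mf(fam, 1.5))
})

test_that("the retained alpha table matches quantiles recomputed from the family member", {
  fam <- arsenic_family(n_mc = 2000, seed = 12)
  mf <- fractile_mf(fam, 0.95, mode = "analytic")
  # empirical recomputation straight from the alpha = 0.4 family member
  sub <- fam[fam$pass == "umf" & abs(fam$alpha - 0.4) < 1e-12, ]
  emp_lo <- quantile(ecdf_of(sub$min), 0.95)
  emp_hi <- quantile(ecdf_of(sub$max), 0.95)
  row <- mf$alpha_table[mf$alpha_table$pass == "umf" &
                          abs(mf$alpha_table$alpha - 0.4) < 1e-12, ]
  expect_equal(row$lo, emp_lo, tolerance = 0.02)
  expect_equal(row$hi, emp_hi, tolerance = 0.02)
})

test_that("constant models give crisp summaries through the whole chain", {
  cm <- hybrid_model(function(a) a, list(a = dist_constant(2.5)))
  fam <- suppressWarnings(propagate(cm, n_mc = 20, seed = 1))
  mf <- fractile_mf(fam, 0.5)
  expect_equal(c(mf$umf$a, mf$umf$d, mf$lmf$a, mf$lmf$d), rep(2.5, 4))
  pb <- pbox(fam, "umf")
  expect_equal(unclass(pbox_variance(pb)), c(lo = 0, hi = 0))
})
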