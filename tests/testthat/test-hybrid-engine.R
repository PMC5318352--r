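test_that("the alpha grid runs to the smallest fuzzy height in 11 levels", {
  g <- make_alpha_grid(arsenic_model())
  expect_equal(g$w, 0.8)
  expect_equal(g$levels, seq(0, 0.8, by = 0.08))

  m1 <- hybrid_model(function(x, y) x + y,
                     list(x = gfn(0, 1, 2), y = gfn(3, 4, 5)))
  expect_equal(make_alpha_grid(m1)$levels, seq(0, 1, by = 0.1))

  m2 <- hybrid_model(function(x, y) x + y,
                     list(x = gfn(0, 1, 2, height = 0.8),
                          y = gfn(3, 4, 5, height = 0.6)))
  expect_equal(make_alpha_grid(m2)$w, 0.6)

  m3 <- hybrid_model(function(z) z, list(z = dist_normal(0, 1)))
  expect_warning(g3 <- make_alpha_grid(m3), "no fuzzy parameters")
  expect_equal(g3$levels, 0)
})

test_that("corner evaluation returns the vertex-method extrema", {
  m <- hybrid_model(function(x, y) x + y,
                    list(x = gfn(0, 0.5, 1), y = gfn(2, 2.5, 3)))
  env <- corner_envelope(m, draw = list(),
                         cuts = list(x = cut_interval(0, 1), y = cut_interval(2, 3)))
  expect_equal(env$min, 2)
  expect_equal(env$max, 4)

  # case-study model at fixed BW: brute force over the 4 corners
  ars <- arsenic_model()
  env2 <- corner_envelope(ars, draw = list(BW = 70),
                          cuts = list(PEC = cut_interval(4, 6),
                                      BCF = cut_interval(35, 55)))
  corners <- expand.grid(pec = c(4, 6), bcf = c(35, 55))
  vals <- mapply(function(p, b) noncancer_risk(p, b, 70), corners$pec, corners$bcf)
  expect_equal(env2$min, min(vals))
  expect_equal(env2$max, max(vals))
  expect_equal(env2$min, 2.3288e-07, tolerance = 1e-4)

  # vertex method misses interior extrema of non-monotone models ...
  nm <- hybrid_model(function(x) x * (1 - x), list(x = gfn(0, 0.5, 1)))
  cut01 <- list(x = cut_interval(0, 1))
  env3 <- corner_envelope(nm, draw = list(), cuts = cut01)
  expect_equal(env3$max, 0) # true maximum is 0.25
  # ... and the dense-lattice refinement recovers them
  env4 <- corner_envelope(nm, draw = list(), cuts = cut01, grid_points = 51)
  expect_equal(env4$max, 0.25, tolerance = 1e-3)
})

test_that("corner envelope agrees with a 50-point dense-grid search on the case-study model", {
  ars <- arsenic_model()
  set.seed(55)
  for (i in 1:100) {
    bw <- rnorm(1, 70, 5)
    alpha <- runif(1, 0, 0.8)
    cuts <- list(PEC = alpha_cut(ars$params$PEC, alpha),
                 BCF = alpha_cut(ars$params$BCF$umf, alpha))
    vertex <- corner_envelope(ars, draw = list(BW = bw), cuts = cuts)
    dense <- corner_envelope(ars, draw = list(BW = bw), cuts = cuts, grid_points = 50)
    expect_equal(vertex$min, dense$min, tolerance = 1e-9)
    expect_equal(vertex$max, dense$max, tolerance = 1e-9)
  }
})

test_that("propagation produces a nested, ordered, reproducible family", {
  fam <- arsenic_family(n_mc = 300, seed = 5)
  expect_s3_class(fam, "cdf_family")
  expect_equal(nrow(fam), 2 * 11 * 300)
  expect_true(all(fam$min <= fam$max))

  levels <- attr(fam, "alpha_levels")
  for (pass in c("umf", "lmf")) {
    sub <- fam[fam$pass == pass, ]
    m <- matrix(sub$min, ncol = length(levels))  # draws x alpha
    M <- matrix(sub$max, ncol = length(levels))
    # per-draw nesting: minima non-decreasing, maxima non-increasing in alpha
    expect_true(all(diff(t(m)) >= -1e-15))
    expect_true(all(diff(t(M)) <= 1e-15))
  }
  # pass ordering at equal draw and alpha: LMF interval inside UMF interval
  umf <- fam[fam$pass == "umf", ]
  lmf <- fam[fam$pass == "lmf", ]
  expect_true(all(umf$min <= lmf$min + 1e-18))
  expect_true(all(lmf$max <= umf$max + 1e-18))

  expect_identical(arsenic_family(n_mc = 300, seed = 5), fam)
  expect_false(identical(arsenic_family(n_mc = 300, seed = 6), fam))
})

test_that("degenerate models propagate to the expected degenerate curves", {
  # constants only: every curve a single step at the constant output
  cm <- hybrid_model(function(a, b) a * b, list(a = 3, b = dist_constant(7)))
  expect_warning(fam <- propagate(cm, n_mc = 100, seed = 1), "no fuzzy")
  expect_true(all(fam$min == 21 & fam$max == 21))

  # single GFN, no randomness: curves are steps at the alpha-cut image ends
  gm <- hybrid_model(function(x) 2 * x + 1, list(x = gfn(4, 5, 6, height = 0.8)))
  fam2 <- propagate(gm, n_mc = 50, seed = 1)
  for (alpha in attr(fam2, "alpha_levels")) {
    cut <- alpha_cut(gfn(4, 5, 6, height = 0.8), alpha)
    sub <- fam2[fam2$alpha == alpha & fam2$pass == "umf", ]
    expect_equal(unique(sub$min), 2 * cut[["lo"]] + 1)
    expect_equal(unique(sub$max), 2 * cut[["hi"]] + 1)
  }
})

test_that("the engine rejects generalized IVFNs and malformed models", {
  gen <- ivfn(umf = gfn(35, 45, 55, height = 0.9),
              lmf = gfn(40, 45, 50, height = 0.8))
  m <- hybrid_model(function(x, z) x * z,
                    list(x = gen, z = dist_normal(1, 0.1)))
  expect_error(propagate(m, n_mc = 10, seed = 1), "generalized IVFN unsupported")
  expect_error(propagate(arsenic_model(), n_mc = 10), "seed")
  expect_error(hybrid_model(function(x) x, list(x = gfn(0, 1, 2), y = gfn(0, 1, 2))),
               "missing|unused")
  bad <- hybrid_model(function(x, z) log(x) * z, # log of a negative corner
                      list(x = gfn(-1, 0, 1), z = dist_normal(1, 0.1)))
  expect_error(suppressWarnings(propagate(bad, n_mc = 10, seed = 1)), "non-finite")
})
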