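---
title: "Hybrid propagation of variability and fuzzy uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid propagation of variability and fuzzy uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzybox)
```

## Why a hybrid method

Risk models rarely face one kind of ignorance. Body weight across an exposed
population is *variable*: more data would not remove the spread, and a
probability distribution is its natural description. A bioaccumulation
factor elicited from experts is *uncertain*: the spread reflects incomplete
knowledge, and pretending it is a sampling distribution manufactures
precision that is not there. Treating everything probabilistically
understates epistemic ignorance; treating everything possibilistically
throws away genuine frequency information. `fuzzybox` keeps the two apart
all the way through the computation and reports results in which the two
kinds of spread remain distinguishable: probability on one axis, membership
level on the other.

Epistemic parameters are represented two ways, in increasing order of
reticence:

* a **generalized fuzzy number** (GFN) `[a, b, c, d; w]` — a trapezoidal
  possibility distribution whose height `w ≤ 1` expresses partial
  confidence in the distribution itself (a triangular number is the case
  `b = c`);
* a **normal interval-valued fuzzy number** (IVFN) — when the expert will
  not commit to a single membership curve, an upper (UMF) and a lower (LMF)
  membership function bound it, each of height 1, with every LMF α-cut
  nested inside the corresponding UMF α-cut.

Membership between knots is linear. The trapezoidal notation does not force
this, but it is the standard reading, every α-cut then has closed-form
endpoints, and it is required for the case-study results below to be exact.

## The propagation algorithm

For a model `M(P₁…Pₘ, G₁…Gₛ, F₁…Fₙ)`:

1. **Sampling.** Each probabilistic `Pᵢ` gets one uniform stream of `n_mc`
   draws, pushed through its analytic quantile function. The streams are
   drawn once, before the α loop, and reused at every membership level and
   in both passes. This is a deliberate design point: with shared draws the
   per-draw output intervals nest *exactly* as α grows, rather than only in
   distribution, and the downstream nesting properties become invariants
   the test-suite can assert at machine precision.
2. **α grid.** `α = 0, w/10, …, w` with `w = min(wₛ, 1)` over the GFN
   heights — 11 levels, both endpoints included. IVFNs entering the engine
   must be *normal*; a generalized IVFN (UMF height below 1) is rejected
   with a distinct error, because below the LMF height and above it the cut
   structure changes and no consistent sweep exists for the method as
   formulated. With no fuzzy parameters at all the grid degenerates to
   `{0}` (pure Monte Carlo) with a warning.
3. **Corner evaluation.** At each α the `s + n` fuzzy parameters become
   closed intervals (α-cuts; the pass decides whether an IVFN contributes
   its UMF or LMF). For every draw the model is evaluated at all `2^(s+n)`
   corners of the interval box and the extrema are kept — the vertex
   method. It is exact when the model is monotone in each fuzzy argument
   (true of the case study, where risk is increasing in both fuzzy inputs),
   and can miss interior extrema otherwise: `propagate(...,
   refine_nonmonotone = TRUE)` substitutes a dense lattice per cut as a
   safety valve, at a cost exponential in the lattice size. The extrema are
   taken per draw across corners, yielding one minima CDF and one maxima
   CDF per (pass, α) — for monotone models this gives the same envelope as
   forming `2^(s+n)` corner CDFs first and enveloping afterwards, and it is
   the construction under which "a pair of CDFs" per level is well defined.
4. **Two passes.** The UMF pass and the LMF pass differ only in which
   membership function each IVFN contributes; GFNs are identical in both.
   The result is a `cdf_family`: 2 passes × 11 levels × 2 curves.

## Summaries

**P-box.** The α = 0 curves of a pass bound every CDF consistent with the
stated uncertainty (wider cuts dominate narrower ones pointwise, so α = 0
suffices). Its summaries are interval-valued:

* *range*: by default the 0.5th percentile of the minima curve to the
  99.5th of the maxima curve. Percentile-based endpoints are used rather
  than sample extremes because the extremes of a finite Monte Carlo run are
  unstable (their distribution never settles as single wild draws come and
  go); both percentiles are exposed as arguments.
* *mean*: `[mean(minima), mean(maxima)]` — sharp, since the mean is
  monotone in each coordinate.
* *variance*: sharp bounds over all selections `xᵢ ∈ [minᵢ, maxᵢ]`. The
  lower bound is 0 exactly when all intervals share a common point
  (typical for p-box intervals, which all straddle the central output
  region); otherwise the minimizing selection clamps every interval to a
  common centre and an `O(n log n)` sweep over candidate segments finds the
  exact minimum. The maximizing selection puts each `xᵢ` at the endpoint
  farther from the selection mean, which makes it a midpoint-threshold
  selection; scanning the `n + 1` thresholds with prefix sums gives the
  exact maximum. The divisor convention (population `1/n` vs sample
  `1/(n-1)`) is configurable; population is the default.

**Fractile membership functions.** At fixed `p`, the quantile interval
`[Q_p(minima), Q_p(maxima)]` per (pass, α) nests as α grows, so the α = 0
interval is the support and the α = w interval the core of a trapezoidal
GFN of height `w` per pass; the two passes together form a completely
generalized IVFN of the output at fractile `p`. All 11 per-α intervals are
retained (`tidy()` returns the table); the 4-knot trapezoid is a summary
whose legs interpolate the knots linearly, and between grid levels it is an
approximation — the true cut endpoints of a product-form model are
quadratic in α, which is visible midway between support and core but does
not affect the knots themselves.

**Quantile modes.** Quantiles can be read from the Monte Carlo ECDFs
(`"empirical"`, generalized-inverse/type-1 convention, matching the
step-function CDF definition) or computed analytically (`"analytic"`): for
a model with a single probabilistic parameter, the corner envelope is a
monotone function of that parameter, so the curve quantile is the envelope
evaluated at the parameter's analytic normal quantile (direction detected
numerically). Analytic mode removes all Monte Carlo noise from the
deterministic summaries and is how the case-study reference values are
reproduced; empirical mode is the general path and agrees with it to
sampling accuracy.

## The arsenic case study

`arsenic_model()` packages non-cancer risk from ingesting
arsenic-contaminated fish: `Risk = CDI / Rfd`,
`CDI = C_f · FIR · FR · EF · ED · CF / (BW · AT)`, `C_f = PEC · BCF`, with
AT = 25550 d, ED = 30 y, EF = 350 d/y, FR = 0.5, FIR = 170 g/day,
CF = 1e-9, Rfd = 3e-4 mg/(kg·day), BW ~ Normal(70, 5) kg,
PEC = `[4, 5, 6; 0.8]` µg/l and BCF the normal IVFN UMF `[35, 45, 55]` /
LMF `[40, 45, 50]` l/kg.

Two modelling choices deserve explanation:

* *Which parameter is random.* The parameter table labels FIR
  "probabilistic" but gives it the single value 170, while only BW carries
  a stated distribution. The model here samples BW and holds FIR at 170 —
  the only assignment consistent with all of the reference summary values
  (every one of which moves with the BW quantiles `70 ± z·5`).
* *Units.* `intake_unit_factor = 1e-3` converts FIR from g/day to kg/day
  inside the intake equation; without it every output is exactly 1000×
  the reference values. The factor is an explicit argument of
  `chronic_daily_intake()` and `arsenic_model()`, never hidden.

```{r case-study}
fam <- propagate(arsenic_model(), n_mc = 5000, seed = 20170131)
glance(pbox(fam, "umf"), mode = "analytic")
glance(fractile_mf(fam, 0.95, mode = "analytic"))
```

With the analytic quantile mode the UMF-pass range is
`[1.96688e-07, 6.72691e-07]` and the 95th-fractile upper membership
function `[2.639e-07, 4.052e-07, 4.429e-07, 6.220e-07; 0.8]` — the values
the acceptance script (`scripts/acceptance.R`) recomputes. The p-box
variance bounds have lower endpoint 0 (the per-draw intervals share a
common point) and an upper endpoint near `3.4e-14` (UMF pass) /
`2.0e-14` (LMF pass) at 5000 draws.

## Numerical and design choices

* **Monte Carlo size.** Default `n_mc = 5000`: summaries of this model are
  stable at that size (the empirical mean bounds sit within a fraction of a
  percent of their analytic limits), and the full two-pass sweep runs in
  well under a second. The test-suite uses 150–5000 draws depending on what
  a test measures; the acceptance script uses 5000.
* **Seeds.** A seed is a required argument of `propagate()` — there is no
  silent default, because an unreproducible risk assessment is not an
  artifact. The packaged config fixes seed 20170131.
* **α-cut arithmetic tolerance.** Cut and membership arithmetic is pure
  floating point on affine expressions; invariant checks use a relative
  tolerance of 1e-9.
* **Degenerate inputs.** A crisp number `gfn(x, x, x, x)` flows through the
  fuzzy path as a constant; zero-width legs take the jump-to-`w` limit
  convention so `alpha_cut()` is total; a constants-only model produces
  single-step CDFs and crisp summaries end to end.
* **Ties.** Empirical quantiles use the type-1 generalized inverse
  throughout, so tied draws collapse into single steps and quantiles are
  always attained sample values.

## What the tests do and do not show

The synthetic models exercised by the test-suite (the arsenic chain and
small algebraic models) are monotone in their fuzzy arguments with a single
probabilistic parameter, which is exactly the regime in which the vertex
method and the analytic quantile mode are exact; the suite verifies the
corner envelope against dense-grid search, the cut formulas against
per-leg interpolation oracles, the variance bounds against endpoint
enumeration, and byte-identical reproduction under a fixed seed. Passing
these tests does not certify behaviour on models that are non-monotone in
a fuzzy argument (use `refine_nonmonotone`), on dependent probabilistic
inputs (not modelled — draws are independent streams), or on distribution
families beyond normal/constant (not implemented). Real elicitation data
also arrive with messier membership shapes than trapezoids; curved
membership functions are out of scope.

## Known limitations

* Generalized IVFN inputs (UMF height < 1) are rejected rather than
  propagated — the method is undefined for them.
* The vertex method's exactness is the user's responsibility to judge (or
  delegate to the lattice refinement); the package documents but cannot
  detect non-monotonicity in general.
* P-box arithmetic (convolving boxes) and second-order Monte Carlo are out
  of scope; the package propagates through a single model evaluation.
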