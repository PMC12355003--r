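---
title: "Methods: diel step-selection analysis around hunting-ban areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel step-selection analysis around hunting-ban areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Large herbivores that are hunted tend to trade forage quality against
perceived risk from humans, and the trade-off flips between day and
night: animals hide in cover or rugged terrain by day and use open,
productive habitat near human infrastructure by night. Spatial hunting
bans (hunting-ban areas, HBAs) change the risk surface and may
concentrate animals inside ban boundaries exactly when hunting pressure
is highest. `dielssf` provides the full analysis chain for quantifying
these patterns from GPS collar data with integrated step-selection
functions (iSSFs), plus a synthetic landscape-and-trajectory generator
so that every stage can be validated against a known truth.

## The model

An iSSF compares each observed movement *step* (the straight segment
between consecutive fixes) with $K$ *available* steps drawn from a
tentative movement kernel: step lengths from a gamma($k$, $\lambda$)
law, turning angles from a von Mises($0$, $\kappa$) law around the
incoming bearing. With end-point covariates $z$ and movement terms
$(\ell, \ln \ell, \cos\theta)$, the probability that the used step is
the one at $x_u$ among its stratum $\{x_1,\dots,x_{K+1}\}$ is

$$
P(u) \;=\; \frac{\exp(\beta^\top x_u)}{\sum_j \exp(\beta^\top x_j)},
$$

a conditional-logistic likelihood in which each stratum has its own
(eliminated) intercept. The movement-term coefficients correct the
tentative kernel — that is the "integrated" part: the updated kernel is
$k' = k + \beta_{\ln \ell}$, $\lambda' = \lambda - \beta_{\ell}$,
$\kappa' = \kappa + \beta_{\cos\theta}$.

`fit_conditional_logit()` maximizes this likelihood by Newton–Raphson
with the analytic gradient and Hessian, starting at $\beta = 0$, with
step-halving on any likelihood decrease, convergence at
$\max|\nabla| < 10^{-8}$ and at most 100 iterations. The covariance is
the inverse negative Hessian; inference is two-sided Wald.

### The Poisson-profile consistency check

The same model can be written as a Poisson regression of the
used/available indicator with one free intercept per stratum. Profiling
the intercepts out of the Poisson likelihood yields the
conditional-logit likelihood up to a $\beta$-free constant
($-n_\text{strata}$), so the two estimators must agree coefficient by
coefficient. `poisson_profile_fit()` implements that second path —
closed-form intercept profiling alternating with Newton steps whose
information matrix is the Schur complement of the intercept block — and
the test suite asserts agreement to $10^{-6}$ on every design it
touches. This is the package's central internal consistency check; an
external cross-check against `survival`'s conditional logit runs in the
test suite as well.

### Random effects across individuals

The original analysis style fits a mixed Poisson model with random
slopes per individual-year. We deliberately replace that with (a) the
exact fixed-effects conditional logit on pooled strata and (b) a
two-stage surrogate: fit each individual-year separately and pool per
coefficient with the DerSimonian–Laird random-effects estimator
(`pool_individual_fits()`), which returns the population mean, its
variance and a between-individual variance $\tau^2$. The two-stage
route is a recognized approximation to random-slope step-selection
estimation; it ignores cross-coefficient covariances (matching how
per-covariate effects are reported) and will differ from a Laplace
mixed fit when individual designs are very small or separation-prone.
We chose exactness and testability over re-implementing an approximate
mixed solver; the divergence is a documented limitation.

The hunting-activity *main* effect deserves a note: hunting activity is
a property of a step's date, hence constant within every stratum, so it
is absorbed by the stratum intercepts and is not estimable in any
matched-stratum design. `hunting_activity_interaction()` therefore
reports the HBA main effect and the HBA-by-hunting interaction — the
estimable quantities that answer whether selection for ban areas
strengthens on hunting days.

## Data preparation

* `resample_track()` — greedy forward selection to one fix every 3 h
  (tolerance 3 min), the common denominator across collar schedules.
  Gaps outside the tolerance open a new burst; the operation is
  idempotent.
* `trim_capture_window()` — drops the first 3 × 24 h (capture stress)
  and the last calendar day (collar removal); half-open retention.
* `screen_gross_errors()` — two-stage screening: R1 flags fixes further
  than `distance_limit` from the coordinate-wise median of up to 10
  neighbours on each side; R2 flags the out-and-back spike signature
  (geometric-mean speed above `speed_limit` and turning cosine below
  `cos_angle_limit`) among R1-clean fixes. The thresholds are not
  printed in the source protocol; the defaults (100 km, 10 km/h,
  −0.97) follow the magnitudes of the published screening method's
  examples and are fully configurable. Flags are recorded, never
  deleted; analysis stages exclude flagged fixes.
* `monthly_fix_filter()` — a month enters the analysis only if the
  achieved fix rate is at least 80 % of the 8/day schedule. The filter
  operates per (animal, month) — excluding the month, not the animal —
  one of two defensible readings of the inclusion rule; both are
  available via the returned rate table.
* `classify_day_night()` — NOAA solar-position algorithm; DAY iff the
  apparent solar elevation is at least −0.833° (refraction plus solar
  radius), so twilight counts as night. The boundary is closed on the
  day side — arbitrary, fixed, and tested. Latitudes beyond ±66.5° are
  rejected rather than mis-classified. Timestamps are UTC throughout.

Home-range inclusion: `kde_ud()` estimates a Gaussian-kernel
utilization distribution (reference bandwidth
$h = \sigma n^{-1/6}$, $\sigma^2 = (\mathrm{var}_x+\mathrm{var}_y)/2$,
exposed in the call), `isopleth_region()` takes the smallest
highest-density cell set holding 99 % of the mass (ties broken by grid
index), and `hba_overlap_filter()` retains an animal iff a member cell
center falls inside an HBA polygon — a cell-center approximation whose
error is bounded by one cell.

## Covariates

All layers share one grid (bilinear resampling for continuous layers,
nearest-cell for categorical — single-grid simplicity over
multi-resolution fidelity). `slope_from_dem()` uses Horn's 3×3 method
with clamped edges. `trail_path_distance()` is a multi-source shortest
path on the 8-connected cell graph with surface-length edge weights
$\sqrt{\text{planar}^2 + \Delta z^2}$ — path distance "accounting for
topography", not planar distance; whether the original GIS workflow
weighted slopes beyond surface length is not recoverable, so
surface-length weighting is implemented and labelled as such.
Continuous covariates are standardized over the rows entering *each*
fit (used and available pooled), the scope recorded in the returned
table; that table also defines the "average habitat" (all standardized
covariates at 0, HBA at "outside") used as the log-RSS reference.

## Inference

`log_rss()` computes $\beta^\top(x_1 - x_2)$ over selection terms with
the delta-method CI ($\pm 1.96\,$se — the normal quantile, matching
Wald convention; random-effect variance is *not* added, which is
labelled in outputs). `holm_adjust()` implements the step-down
correction with an explicit family size `m` that may exceed the list
supplied: the original families (264 and 48 tests) span several model
files and cannot be reconstructed uniquely from the text, so the family
size is a recorded input rather than something the package guesses.
`monthly_effect_grid()` classifies each month × diel × covariate effect
as positive / negative / nonsignificant at the Holm-adjusted 5 % level;
`september_hba_contrast()` fits the covariate-by-HBA interaction model
on September strata and draws paired log-RSS curves, each level
referenced to the average habitat *at that level*, so both curves pass
through zero at the reference.

## The synthetic world

`generate_landscape()` emulates the inputs of an alpine study area on a
square extent (default 5 km at 50 m cells): elevation is a smoothed
Gaussian random field (correlation length 400 m, sd 350 m around
1500 m) plus a V-shaped cross-valley trend of 0.25 m/m; tree cover is a
logistic transform of a second field correlated at $\rho = -0.4$ with
elevation (denser forest on valley flanks), clipped to [0, 100] %; 1–3
trails follow low-elevation paths west to east; 1–3 rectangular HBAs
cover 10–30 % of the extent; the hunting calendar marks Sep 1 – Oct 20
each year, inside the Aug 15 – Oct 31 analysis window, so both activity
levels occur in the window. The reference coordinates (46.6° N,
10.2° E) sit in the eastern Alps. Where the source protocol states no
value (field smoothness, valley gradient, trail count), the defaults
were chosen once as plausible for mountain terrain and are not tuned.

`simulate_issf_track()` draws, at each step, `M = 200` candidates from
the movement kernel and selects one with probability
$\propto \exp(\beta^\top z)$, with $\beta$ switching between the day
and night vectors according to the shared solar classifier at the
step's start time. This is an importance-sampling approximation of the
exact redistribution kernel; its fidelity grows with `M`, which is
configurable. Candidates outside the extent get zero weight (bounded
terrain, no torus wrapping); if all `M` fall outside, the draw is
retried up to 50 times before the simulation aborts naming the step.
HBA membership of a candidate is evaluated at its end point only,
matching the end-point covariate extraction of the fitting stage. The
first heading is uniform on $[-\pi, \pi)$. Start positions are placed
by the caller; nothing constrains them relative to HBA borders, so the
HBA-availability balance of a synthetic run need not match any real
study area.

What the generator does *not* emulate: terrain hydrology, multi-animal
interaction, barrier effects, home-range fidelity, habitat-dependent
fix failure (dropout in `corrupt_track()` is independent per fix).
Passing tests therefore demonstrate the estimators' correctness under
the stated model, not robustness to every pathology of field data.

## Numerical choices and degenerate inputs

* Conditional-logit convergence: gradient max-norm $10^{-8}$, 100
  iterations, step-halving; per-stratum max-subtraction keeps the
  log-sum-exp stable. $|\beta_j| > 15$ raises a separation warning.
* Identifiability: columns constant within every stratum are detected
  by comparing within-stratum-centered column norms against the raw
  column scale (a plain QR tolerance misses columns that are tiny from
  the start); remaining collinearity is caught by pivoted QR, and the
  offending term is named in the error.
* Gamma MLE: Newton on the digamma score with the Choi–Wette start;
  zero-length steps are replaced by half the minimum positive length
  before the log transform (logged). Von Mises $\kappa$: Bessel-ratio
  inversion with the standard series starts; a mean cosine at 1 is a
  degenerate-concentration error, and a negative mean cosine floors
  $\kappa$ at 0.
* First step of a burst: the turning angle is undefined; the stratum is
  retained with the used-row cosine imputed as 0 and a `first_step`
  flag (movement terms are never standardized), and available bearings
  are drawn around a uniform heading.
* Strata lose available rows whose end points leave the rasters; a
  stratum survives while its used row and at least one available row
  remain, and drop counts are reported.
* Isopleth ties are broken by grid index (stable sort), making regions
  reproducible and nested across levels.

## Problem sizes used in the shipped checks

The test suite and the acceptance script validate at sizes chosen to
make the statistical assertions sharp while staying lightweight: one
simulated 3 000-step trajectory (about 1 500 strata per diel class) for
coefficient recovery within 3 se; 200 replicates of 1 000 strata for
Wald coverage in [0.90, 0.98]; 5 000 steps for movement-kernel
updating within 10 %; 10×10 rasters against a brute-force Dijkstra;
1 000 random (latitude, date, time) triples against an independent
almanac algorithm. These sizes are the package's own validation
choices and can be scaled up by editing one constant each.
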