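---
title: "Methods: dynamic factor analysis of salmon body-length synchrony"
author: "salmosync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic factor analysis of salmon body-length synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

salmosync asks a population-ecology question: when the mean body length
of returning Atlantic salmon changes over decades, do rivers hundreds of
kilometres apart change together?  Shared (synchronous) change points to
broad-scale drivers acting on the ocean feeding grounds — climate,
thermal habitat, prey, competitor density, fisheries — while
river-specific change points to local causes.  The package provides the
full chain: building river-by-year mean fork-length panels from
individual fish records, estimating shared latent trends by dynamic
factor analysis (DFA), testing which rivers changed credibly, clustering
rivers by their trend loadings, and asking whether candidate marine
covariates explain the shared signal.

# The model

For $S$ rivers observed over $T$ years, let $y_t$ be the length-$S$
vector of mean fork lengths (mm) in year $t$, centered on each river's
long-term mean.  The DFA is a linear-Gaussian state space model

$$ y_t = Z x_t + a + D d_t + v_t, \qquad v_t \sim \mathrm{N}(0, R), $$
$$ x_t = x_{t-1} + w_t, \qquad w_t \sim \mathrm{N}(0, I_m), $$

with $m$ latent common trends $x_t$ following independent random walks,
an $S \times m$ loading matrix $Z$, optional river offsets $a$ (fixed
at zero for centered panels), optional annual covariates $d_t$ with
river-specific coefficients $D$, and structured observation error $R$:

* `diagonal_equal` — one shared variance, no covariance (1 parameter);
* `equalvarcov` — one shared variance and one shared covariance
  (2 parameters), $R = (\sigma^2 - c) I + c J$;
* `diagonal_unequal` — river-specific variances, no covariance
  ($S$ parameters).

Missing river-years are handled exactly, by reducing the observation
vector to the observed rows at each filter step.

## Identifiability and initial state

A factor model is only identified up to an invertible mixing of trends
and loadings.  We adopt the standard DFA convention: the trend
innovation covariance is fixed at $I_m$ (loadings carry the scale) and
entries of $Z$ above the diagonal are constrained to zero during
estimation.  After fitting, a varimax rotation of $Z$ (with the inverse
rotation applied to $x_t$ and its covariances) gives the interpretable
basis; fitted values are invariant to this rotation to machine
precision, which the test suite asserts at $10^{-10}$.

The initial state $x_0$ is treated as a fixed parameter with zero prior
variance, so $x_1 \sim \mathrm{N}(x_0, I)$.  This avoids the ambiguity
of diffuse-prior likelihoods and makes the likelihood identical to the
dense joint-normal density of the stacked observations
($\mathrm{Cov}(y_{it}, y_{ju}) = \min(t,u)\, z_i' z_j + R_{ij}
\mathbf{1}(t=u)$), which `loglik_exact()` evaluates directly as an
independent oracle.  Absolute log-likelihoods under other initial-state
conventions differ by a constant-free reparameterization; all
comparisons inside the package use this one convention.

## Estimation

`fit_dfa()` maximizes the likelihood by an expectation/conditional
maximization algorithm.  The E-step is a Kalman filter and
Rauch–Tung–Striebel smoother (compiled, with row-reduction at missing
observations).  Three conditional M-steps follow: the initial state
($x_0 \leftarrow \hat x_{1|T}$), a joint generalized-least-squares
update of the free entries of $(Z, a, D)$ from the expected normal
equations (Kronecker products of smoothed state moments with the
embedded $R^{-1}$, accumulated by missingness pattern), and the $R$
update.  For the diagonal structures the $R$ update is closed-form; for
`equalvarcov` the two parameters are optimized numerically in a
reparameterization $(e_1, e_2) = (\sigma^2 - c,\ \sigma^2 + (S-1)c)$
whose positivity guarantees a valid covariance for every observed
subset size.  A log-scale barrier keeps both eigenvalue families in
$[10^{-8}, 10^{8}]$ times the data variance: on small, heavily
parameterized panels the profile likelihood is otherwise unbounded as
the within-year residuals collapse onto the constant vector.  Each step
maximizes the same expected complete-data log-likelihood, so the
observed log-likelihood is non-decreasing; tests assert this with
$10^{-8}$ slack on every iteration.

Convergence is declared when the absolute log-likelihood change falls
below `tol` (default $10^{-6}$) within `max_iter` iterations (default
50,000; smaller caps are used in the simulation studies below, where
the smoothed trends stabilize long before the final likelihood tick).
Hitting the cap returns a fit flagged `converged = FALSE` rather than
an error; model selection drops such fits.

## Model selection

All combinations of 1–4 trends and the three error structures are
ranked by AICc, $-2\log L + 2Kn/(n-K-1)$, with $n$ the number of
non-missing observations (a `total` switch uses $S \times T$) and $K$
counting free loadings ($Sm - m(m-1)/2$), error parameters, the $m$
initial-state values, and $S$ coefficients per covariate.  Ties within
2 AICc are broken by preferring models without an *unimportant trend* —
one whose largest absolute varimax-rotated loading is below 0.2 in
units of the panel's pooled observation SD — and then by fewer
parameters.  The 0.2 figure quantifies the informal "small loadings"
screen; it is configurable.

## Significance of river-level change

DFA does not test change by itself.  `significant_changes()` scans each
river's fitted trajectory $\hat z_i' \hat x_t$ with a 95% band obtained
by the delta method through the smoothed state covariance
($\mathrm{se}_{it} = \sqrt{z_i' V_{t|T} z_i}$; loading uncertainty is
not propagated, matching the usual DFA presentation).  A river changes
significantly when maximal runs of years with the band entirely above
*and* entirely below zero both exist — the river was credibly below its
long-term mean in one period and credibly above it in another.  The
change magnitude is the difference between the largest fitted value in
above-runs and the smallest in below-runs, and the percent change
refers it to the river's raw mean length.  Requiring both signs is the
default because every worked case we reproduce behaves this way; a
switch accepts any two excluding-zero runs.  The rule operates strictly
on the centered scale and rejects non-centered input.

## Clustering and the gap statistic

With more than one trend, rivers are clustered on their loadings:
columns centered and scaled, Euclidean distances, complete linkage.
The number of clusters is chosen by the gap statistic against a
uniform-box reference (100 draws by default, seedable) over
$k = 1, \dots, \min(6, S-1)$, with the Tibshirani one-SE rule.

## Covariates

Candidate drivers enter one at a time ($p = 1$), because the candidate
set is strongly collinear; each adds one coefficient per river.
`evaluate_covariates()` reports the AICc difference to the base model
(negative = improvement), the log-likelihood, and per-river
coefficients with 95% confidence intervals.  The conventional
preference threshold — improvement larger than twice the added
parameters, $2S$ — is reported alongside, but covariates with any AICc
improvement and higher log-likelihood are flagged, since a covariate
tied to only a few rivers can be real yet fail the $2S$ bar.
Coefficient standard errors come from the observed information: a
numerical Hessian of the Kalman log-likelihood over the $D$ block at
the MLE, other parameters held at their estimates.  This conditions on
the nuisance parameters and can be slightly anti-conservative; the
recovery simulations in the test suite show interval coverage adequate
for the screening use made of it.

# Marine covariate construction

**Thermal habitat.**  Monthly 1-degree SST and sea-ice fields are
converted to a growth-potential weight per cell-month: 0 below 1 °C,
rising linearly to 1 at 6 °C, flat to 14 °C (first year at sea) or
12 °C (second year), falling linearly to 0 at 18 °C (first) or 15 °C
(second), 0 above, and 0 whenever ice concentration is at least 0.5.
Boundary conventions: the weight is 0 at exactly 1 °C (ramp start) and
the ice cutoff is inclusive.  Weights are multiplied by spherical cell
areas ($R^2 \Delta\lambda (\sin\varphi_N - \sin\varphi_S)$,
$R = 6371$ km), summed over the age-specific polygon (first year
45–61° N, 64–40° W; second year extended to 70° N west of 45° W, 66° N
east of it, and east to 6° W — the 45° W split at Cape Farewell is a
choice, and configurable, because the Labrador/Irminger boundary is not
exact), and aggregated over the season window (first-year summer
Aug–Nov, winter Dec–Apr, second-year summer May–Nov).  Monthly totals
are *averaged* across the window by default so the index is an area in
km² comparable across windows of different lengths; a `sum` switch
accumulates instead.  Winter windows are labelled by the January year,
and cells with no SST in any month are treated as land.  An explicit
alignment table (`sea_year_alignment()`) maps window years to return
years, e.g. a 1SW fish returning in year $t$ had its first marine
summer in $t-1$.

**Food availability.**  Annual zooplankton and Capelin biomass series
are combined by PCA over their overlapping years (centered and scaled);
the PC1 score is the index, with its sign fixed so that low biomass is
negative (positive loading sum), and the variance-explained fraction —
the leading correlation eigenvalue over the number of series — is
reported.

**Density.**  Pre-fishery abundance (PFA) reported on 1 August is
back-adjusted to 1 January by the assumed natural mortality of 0.03 per
month over 7 months, $e^{0.21}$.  The first-sea-year index sums the
North American maturing and non-maturing components by smolt cohort
(then adjusts); the second-year index adds the southern European
non-maturing PFA (already on a 1 January basis) to the adjusted North
American non-maturing component.  Missing components propagate.

**Exploitation.**  The West Greenland rate is catch over the North
American non-maturing 1SW PFA (1 August basis by default, a `jan1`
switch adjusts first).  The homewater rate is the summed Newfoundland,
Labrador and Saint-Pierre-et-Miquelon catch over *catch plus*
size-specific returns — the standard exploitation-rate form, bounded in
$[0, 1]$, chosen because returns are counted after the fishery and a
raw catch/returns ratio can exceed 1; a `returns` switch preserves the
literal ratio.

**Climate.**  Calendar-year means (AMO) are labelled by that year;
December–March means (NAO) are labelled by the January–March year.
All covariates are z-scored (n−1 SD) before entering the DFA, with the
transformation stored for inversion.

# Data preparation rules

Records positively identified as hatchery, captive-breeding /
supplementation, or aquaculture fish are excluded; unknown origin is
retained as wild (only positively identified non-wild fish are
removed).  Then: sea-age selection, year-range crop, removal of
river-years with fewer than 10 fish of the age class, removal of rivers
with fewer than 20 qualifying years — in that order, because the
20-year count is defined on the cleaned data.  In river-years lacking
scale ages, unaged fish under 630 mm are relabelled 1SW (strict
inequality) *before* the 10-fish screen, so relabelled fish count
toward it.  Panel cells are arithmetic means; missing cells are an
explicit `NA`, never zero; centering stores the river means so it is
exactly invertible.

# The synthetic-data generator

All tests run on synthetic data with known truth.  `dfa_truth()` /
`simulate_panel()` generate panels from the same state-space form the
estimator assumes: by default 19 rivers over 1971–2021 (51 years),
three unit-innovation random-walk trends, loadings uniform on
(−2, 2) mm, offsets near the 543 mm mean 1SW fork length, 15 mm
observation noise, and 20–51 observed years per river placed as
contiguous head/tail blocks — the pattern river monitoring programmes
actually produce, and the one that stresses the smoother most (block
gaps leave whole eras of a river unobserved, unlike scattered holes).
`simulate_grid()` produces a smooth SST climatology with a seasonal
cycle, a linear warming trend and white noise, with ice derived from
SST; `simulate_covariates()` produces stationary AR(1) series.  All
generators are pure functions of their specification and seed.

What the generator does **not** emulate: sampling error in the annual
means (cells are treated as exact), spatially correlated observation
error with geographic structure, non-Gaussian length distributions,
real ocean dynamics, or survey sampling layouts.  Passing tests
therefore demonstrate that the estimator and decision rules work when
the model's assumptions hold at realistic sizes — not that those
assumptions hold for any particular monitoring data set.

# Problem sizes and numerical tolerances in the test suite

The oracle-equivalence checks use complete panels up to 5 × 6 at
$10^{-6}$; EM monotonicity runs 20 panels of 10 rivers × 30 years;
trend recovery runs 20 study-scale panels (19 × 51, three trends,
capped at 3,000 EM iterations); selection consistency runs 20
single-trend panels of 8 rivers × 40 years over a 1–3 trend grid;
the significance rule is calibrated on 20 + 20 panels of 6 rivers ×
30 years with a 50 mm ramp over 20 years against a flat truth, both at
10 mm noise.  These sizes are the package's chosen compromise between
statistical resolution and routine-test turnaround.

# Known limitations

* **Per-trend identifiability at low signal-to-noise.**  With weak,
  unstructured loadings (uniform on (−2, 2) mm) and 15 mm noise, the
  *fitted values* and the leading trend direction are well determined,
  but the individual trend axes are not: the likelihood is nearly flat
  under rotations mixing the weaker trends, and even the smoother run
  at the true parameters cannot pin them down.  Per-trend correlation
  with a simulation truth is therefore an optimistic target at this
  noise level, and `trend_recovery()` offers a Procrustes-aligned
  variant that measures subspace recovery without penalizing the
  arbitrary basis.  Real panels with strong, spatially patterned
  loadings are considerably better behaved.
* **The CI-run significance rule is anti-conservative on trend-free
  panels.**  When the truth has no trend at all, maximum likelihood
  still attributes the smoothed cross-river noise mean to a small
  common trend (an ordinary overfitting effect: a handful of
  log-likelihood units for the extra loading parameters), and because
  the bands condition on the estimated parameters, that spurious
  wander can exclude zero on both sides.  In simulation the false-flag
  rate on flat-truth panels grows with the number of rivers — roughly
  one in five rivers at 6 rivers x 30 years and essentially all rivers
  at 19 x 51 with 10 mm noise — while detection of a genuine 50 mm
  shift exceeds 90%.  Treat the rule as a screen for *which* rivers
  changed and by how much, given that trends exist, not as a test of
  the global null of no change; pairing it with an independent
  trend test on suspect rivers is prudent.
* The `unconstrained` error covariance is deliberately not offered;
  with realistic missingness it rarely converges and invites the
  degeneracy the `equalvarcov` barrier guards against.
* Coefficient intervals condition on $(Z, R, x)$ at their MLEs.
* The GAM cross-check of trend significance used in some analyses of
  this kind is out of scope; the CI-run rule here is the conservative
  primary test.
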