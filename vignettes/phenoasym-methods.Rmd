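---
title: "Methods: asymmetric senescence responses to autumn warming and cooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: asymmetric senescence responses to autumn warming and cooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
conventions behind `phenoasym`, and what its synthetic-data tests do and do
not demonstrate about real observations.

## The scientific model

The package's core quantity is the sensitivity of the autumn leaf senescence
date (LSD) to preseason temperature, estimated separately for units (sites
or grid cells) experiencing autumn *warming* versus autumn *cooling*, with
the hypothesis of interest being asymmetry: a stronger response (more days
per °C) under warming than under cooling. The chain is:

* LSD from greenness trajectories (two independent dating rules, averaged);
* per-unit climate drivers over a data-selected preseason window;
* per-unit regression sensitivities (ridge on normalized anomalies and
  unscaled multiple linear regression);
* group contrasts between warming and cooling regimes;
* propagation to autumn productivity and an area-weighted carbon-bias
  estimate.

## Senescence extraction

**Double logistic.** We fit
$y(t) = a + b\left(\frac{1}{1+e^{c(t-d)}} + \frac{1}{1+e^{e(t-f)}}\right)$
with the sign convention $c<0$, $e>0$, enforced through box constraints in a
Levenberg–Marquardt fit, so that $d$ and $f$ are the green-up and senescence
inflection days and $d<f$ is required for convergence. Under this convention
the off-season level of the curve is $a+b$ and the summer plateau $a+2b$;
$a$ is an offset and $b$ the seasonal amplitude. Initialization is
data-driven ($b_0$ = 95th − 5th percentile, $a_0$ = 5th percentile − $b_0$,
inflections at the extreme first differences, rates ∓0.1 d⁻¹) with a
deterministic set of jittered restarts ((0,0), (−15,+15), (+15,−15),
(−30,+30) days on the inflections); the lowest-SSE converged fit wins. Fits
with $b \le 10^{-5}$ or $d \ge f$ are marked non-converged and excluded.

**Second-derivative rule.** For an isolated logistic decline the second
derivative has local maxima at $f \pm \ln(2+\sqrt3)/e$; we evaluate the
analytic second derivative on a daily integer grid restricted to day-of-year
> 182 and return the *second* local maximum by date (the post-inflection
shoulder). A single maximum in the window is returned but flagged; none is a
method failure for that year.

**Dynamic threshold.** The annual ratio
$(v - v_{\min})/(v_{\max} - v_{\min})$ is computed on the *smoothed
observation series* (not the fitted curve — the rule is an independent
alternative to the fit), and the date of the first downward 0.5 crossing
after the annual maximum is linearly interpolated between bracketing
observations. For a noise-free logistic decline this crossing sits exactly
at $f$.

**Combination and rounding.** The reported LSD is the arithmetic mean of the
two dates, rounded half-up; if one rule fails the other is used alone and
flagged. All reported dates are integer day-of-year, 1-based, with leap
years following the real calendar; dates are handled as calendar dates
internally and converted to day-of-year only at the edges.

**Preprocessing.** Snow-flagged values are replaced by the across-all-years
December–February snow-free mean; the rule is applied to flagged values in
any season, since restricting it to winter would leave corrupted values
standing. Series are then reconstructed with a Savitzky–Golay filter
(default window 7 observations, order 3 — at the default 15-day cadence a
105-day window, wide enough to suppress residual snow spikes while an
order-3 polynomial preserves the senescence shoulder). Cells with mean
annual greenness below 0.1 are excluded (strict inequality; a mean exactly
at 0.1 is kept). In-situ LSD series are filtered once (no re-iteration) by
the median-absolute-deviation rule with $k = 2.5$ and no consistency
constant; when MAD = 0 with non-identical values, only values equal to the
median are retained and the degenerate case is flagged.

## Climate metrics

Cold-degree days accumulate $\max(T_{base}-T_{daily},0)$ from July 1 to the
year's own extracted LSD (not the unit-mean LSD), at $T_{base}$ 5/10/15 °C.
The July 1 anchor presumes extratropical northern-hemisphere seasonality;
no southern-hemisphere rule is defined. Preseason statistics are computed
over windows ending at the anchor day (the unit's MAD-filtered mean LSD).
Frost days use a strict $T_{min} < 0$ °C. Monthly SPEI is averaged over
every month that any window day touches (any-overlap rule — the window is
daily-defined while SPEI is monthly, and partial months carry information).
The frost risk index is the min–max standardization of per-unit mean frost
counts over the pooled analyzed population, 0 everywhere when degenerate.

## Regimes and sensitivities

A unit-period is *warming*/*cooling* when the OLS trend of its Sep–Nov mean
temperature on year is significant (default α = 0.05, defaulted values are
logged in the run manifest) with the matching sign; otherwise *none* and
the unit is excluded from regime contrasts (counted in the manifest).
Period-shift classification requires both sub-period regimes significant
and opposite. The moving-window variant slides a 15-year window one year at
a time.

The optimal preseason is selected from lengths 8–120 d in steps of 8 d by
the largest $|$partial correlation$|$ of LSD with window-mean temperature,
controlling window precipitation sum and radiation mean
(residual-on-residual formulation, $t$ test on $n-4$ df), among windows
significant at α; ties go to the shortest window (parsimony), and a unit
with no significant window is excluded and counted.

Ridge sensitivities: anomalies of the response and each covariate are
min–max scaled to [0,1] per variable ("normalized (0–1) anomalies"; z-score
normalization was the alternative reading — min–max was chosen as the
literal one and gives dimensionless coefficients in a common range), the
design is centered, and the ridge solution is computed by SVD. The penalty
defaults to the generalized-cross-validation minimizer per unit because no
single penalty is defensible across units of different noise levels; a
fixed override is available and recorded. The SE is a seeded 1,000-resample
case bootstrap. MLR sensitivities are unscaled OLS on the same three
covariates, in days/°C, with exact rank-deficiency detection.

Group asymmetry uses Student's (equal-variance) two-sample *t* test on
unit-level sensitivities; slope comparisons use the interaction term of
$y \sim x \times \text{regime}$; metric contrasts use
`metric ~ regime + (1 | biome)` with Satterthwaite degrees of freedom,
degenerating to OLS (flagged) with a single biome; the random-slope variant
groups by coordinates binned to 1° cells, since continuous coordinates are
not estimable as grouping factors.

## The synthetic generator

The generator defines the study conditions the tests run under. Daily mean
temperature is a mid-latitude sinusoid (8 ± 12 °C, peak mid-July) plus the
regime's planted linear trend plus AR(1) noise (lag-1 0.7, typical synoptic
persistence; marginal SD 2 °C). The trend (default ±0.1 °C yr⁻¹) starts at
zero in the first year rather than being centered, and the hinge anomaly
$\Delta T_y$ is measured against the deterministic seasonal climatology.
These two linked choices are what make regime-level asymmetry recoverable:
with anomalies measured against each unit's own period mean, every unit
sees both anomaly signs symmetrically and any hinge response averages to
the same mixture slope in both regimes. Against a fixed climatology,
warming units spend most years on the warm branch and cooling units on the
cool branch — the structure the analysis assumes.

True LSD is $\text{base} + s\,\Delta T_y + \varepsilon$ with
$s = 7.5$ d/°C for $\Delta T_y > 0$ and $3.3$ d/°C otherwise (a
piecewise-linear hinge at zero — the simplest form consistent with two
regime-specific linear sensitivities), base day 285, driving window 40 d,
$\varepsilon \sim N(0, 5\text{ d})$ (within-site interannual LSD noise is
not constrained by published records; 5 d is a free choice exposed in the
configuration). Greenness is the forward double logistic sampled at 15-day
cadence with the senescence inflection at the year's true LSD (so the
threshold rule dates the truth exactly in the noise-free limit), plus
observation noise (SD 0.02) and winter snow corruption (probability 0.3,
multiplicative U(0.1, 0.5), flagged). The mean–minimum temperature offset
is calibrated by solving
$\mathbb{E}[\text{frost days}] = \sum_d \Phi((\text{offset}-\mu_d)/\sigma)$
for the configured expected preseason frost count (default 2 d yr⁻¹);
linearity of expectation makes the calibration exact under AR(1)
dependence. SPEI is generated directly as a standardized index
(N(mean, 1) truncated to [−3, 3]); computing SPEI from water balances is
out of scope. Autumn productivity is
$300 + 2\,(\text{LSD}-285) + 3\,T^{aut}_{anom} + N(0,10)$ g C m⁻² per
autumn, so productivity inherits the LSD asymmetry with a planted coupling
of 2 g C m⁻² per day of delay; a daily GPP series distributing each year's
value over September–November feeds the aggregation code.

What the generator does **not** emulate: spatial autocorrelation between
sites (independent by construction), radiative-transfer realism, mixed
species composition within sites, trend–variance coupling, or realistic
drought persistence in SPEI. Passing tests therefore demonstrate the
correctness and statistical calibration of the machinery under the planted
structure, not that real forests behave this way.

## Numerical conventions and degenerate inputs

* Rounding of dates: half-up, everywhere a date is reported.
* The threshold rule requires the annual max to exceed the min; flat series
  are refused, and zero-amplitude fits are non-converged.
* `linear_trend` on an exactly constant series returns slope 0, p = 1.
* Zero-variance covariates are dropped from ridge fits (warned and
  recorded); a zero-variance temperature covariate or response is an error.
* Seeds: every generator stage derives its own 32-bit stream from the
  master seed, an operation salt and the site index, so stages are
  individually reproducible and independent; bootstrap streams are
  restored after use.
* Problem sizes: unit tests use 1–8 sites and 7–30 years; the end-to-end
  and acceptance runs use the standard 100-cell × 30-year grid, which is
  the scale at which the regime t-test is decisively powered.

## Known limitations

* The derivative rule's date carries the systematic offset
  $\ln(2+\sqrt3)/e$ from the inflection, inflated further when smoothing
  flattens the decline; the combined LSD therefore sits a few days after
  the threshold date by construction. This mirrors the method definition,
  not a bug.
* With a planted trend, neighbouring preseason windows are nearly collinear
  through the shared trend, so window selection under trending climates is
  identified mainly by the noise component; recovery of the exact planted
  window is demonstrated under trend-free conditions.
* Overlapping moving windows from one unit are reported as separate regime
  samples; no overlap deduplication or spatial-autocorrelation correction
  is applied, and no multiple-testing correction across units is made.
* The uncertainty on the carbon-bias total is the spread across
  productivity sources when several are analyzed; no formal error
  propagation is claimed.
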