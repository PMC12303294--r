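---
title: "Multistage models of age-specific cancer incidence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage models of age-specific cancer incidence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multistagefit)
```

## The model family

The age-specific incidence rate $I(t)$ — new cases per 100,000 persons per
unit time at age class $t$ — is, mathematically, the hazard of disease
onset. Multistage carcinogenesis theory treats onset as the completion, in
a fixed order, of $r$ discrete, irreversible, rate-limiting molecular
events (driver mutations, epimutations, rearrangements), the $i$-th
occurring with probability $k_i$ per unit time. When every $k_i t$ is small
over the observed age range, the probability that the first $r-1$ events
have all occurred by time $t$ in any order is
$(k_1 t)(k_2 t)\cdots(k_{r-1}t)$, of which only one of the $(r-1)!$
orderings counts; the hazard is that ordered probability times the rate
$k_r$ of the final event:

$$I(t) \approx k\,t^{\,r-1}, \qquad
  k = \frac{k_1 k_2 \cdots k_{r-1}}{(r-1)!}\,k_r,$$

giving the linear log-log law $\ln I(t) = (r-1)\ln t + \ln k$. The slope
counts events (minus one); the intercept is the log of the aggregated
sequence probability. `linear_params()`, `multistage_rates()`,
`aggregate_k()` and the two event-probability functions implement exactly
this calculus.

Two curved generalizations capture systematic departures from the straight
line:

* **convex upwards** (bending down at older ages):
  $\ln I(t) = a_0 + a_1 \ln t + \ln(1 - a_2 t^{a_3})$, valid only while
  $a_2 t^{a_3} < 1$;
* **concave upwards** (bending up):
  $\ln I(t) = a_0 + a_1 \ln t + \ln(1 + a_2 t^{a_3})$.

Each admits two mechanistic readings (`map_curved_to_mechanistic()`):

* **heterogeneity** — two subgroups/pathways with sequence probabilities
  $k_p, k_q$ and age-scaling exponents $p, q$ sharing $r$ steps:
  $a_0 = \ln k_p$, $a_1 = r + p - 1$, $a_2 = k_q / k_p$, $a_3 = q - p$;
* **age-related effect** — a single pathway ($a_1 = r - 1$) modified by a
  decelerating factor $(k_d, d)$ for the convex form or an accelerating
  factor $(k_a, a)$ for the concave one, with $a_2 = k_d/k$ (or $k_a/k$)
  and $a_3 = d - r + 1$ (or $a - r + 1$).

Under the heterogeneity reading $a_1$ pins down only the sum $r + p$, so
the caller must fix one of $r$ or $p$; the package refuses to guess.
Throughout, logarithms are natural, and incidence is used in its native
per-100,000 scale — the intercept absorbs the unit, which is how the
reference coefficient tables are expressed.

## Age classes and time rescaling

Registry age groups have unequal widths (0–14, 15–39, then 5-year bands).
The package follows the integer age-class convention: groups are numbered
1, 2, 3, … with unit spacing, and original labels are kept as metadata
only. Changing the time unit by a factor $w$ multiplies every per-event
rate by $1/w$ and hence divides $k$ by $w^{r-1}$: only the intercept
moves, never the slope (`rescale_time()`), and predictions and $R^2$ are
invariant. That is what licenses the integer renumbering. When the
youngest class has zero incidence in **both** genders, it is treated as a
structural zero and dropped, with the next class becoming class 1
(`assign_age_classes()`); a zero in only one gender is left in place and
excluded at fit time with a warning.

## Fitting

`fit_linear()` is ordinary least squares of $\ln I$ on $\ln t$; nothing
more is needed. $R^2$ is always computed on the log scale, which is also
the scale on which models are compared.

`fit_curved()` uses a staged, hybrid procedure rather than a black-box
four-parameter optimization:

1. **Anchor scan.** The earliest $m$ points ($m = 3 \dots n-2$, chosen to
   maximize the anchor OLS $R^2$) serve as the approximately linear part
   of the curve — earliest, because in the parameter regimes of interest
   the curvature term grows with age.
2. **Anchor OLS** gives starting values for $(a_0, a_1)$.
3. **Algebraic curvature solve.** Later-point residuals $d_t$ from the
   anchor line satisfy $d_t = \ln(1 \mp a_2 t^{a_3})$ under the model, so
   $\ln(1 - e^{d_t})$ (convex) or $\ln(e^{d_t} - 1)$ (concave) is linear
   in $\ln t$ with intercept $\ln a_2$ and slope $a_3$; with exactly two
   usable points this is the exact two-equation solution. At least two
   later points must have residual signs compatible with the requested
   curvature — otherwise the data simply do not carry that curvature and
   the fit refuses with a mismatch error.
4. **Refinement.** Because the curvature term is generally *not*
   negligible on the anchor points (with $a_2 = 0.73$, $a_3 = 0.14$ it
   contributes $\ln 0.27 \approx -1.31$ already at $t = 1$), the initial
   estimates are polished: first by alternating the two linear solves
   over all points, then by minimizing the residual sum of squares over
   $(\ln a_2, a_3)$ alone with $(a_0, a_1)$ always profiled out by OLS
   (Nelder–Mead with a small multi-start grid, then BFGS, then simplex
   restarts). $(a_0, a_1)$ thus never leave the linear-regression world,
   and on noise-free model data the generating coefficients are recovered
   to near machine precision.

Two numerical facts shape stage 4. The profiled RSS surface has a
degenerate ridge at $a_3 \to 0$ (the curvature term becomes a constant
that the intercept absorbs), which a local search can fall into; the
multi-start grid over the curvature magnitude at the oldest age guards
against it. And the concave model is exactly symmetric under
$(a_0, a_1, a_2, a_3) \to (a_0 + \ln a_2,\; a_1 + a_3,\; 1/a_2,\; -a_3)$
— both branches produce identical predictions — so fits are canonicalized
to $a_3 > 0$, the branch in which curvature grows with age.

`select_model()` fits all three models (curved failures are recorded, not
fatal) and picks the highest $R^2$, except that the two-parameter linear
model wins whenever it comes within `tie_tolerance` (default 0.005) of
the best curved $R^2$. The default is deliberately small: with the high
$R^2$ values typical of log-scale incidence fits, 0.005 is enough to stop
a two-extra-parameter model from winning on noise alone, while a real
curvature term (which changes predictions by tenths on the log scale)
clears it easily.

## Synthetic data

`generate_series()` adds Gaussian noise on the ln-incidence scale
(multiplicative lognormal on the natural scale). This is a design choice,
not an empirical claim about registry variance: it is the error model
conjugate to least squares on the log scale, so parameter-recovery
studies measure the fitting machinery rather than a model/noise mismatch.
Real registry rates have denominator-driven, roughly Poisson counting
error, age-group widths that vary, and cohort effects; none of these are
emulated, so passing recovery tests here validate the algorithms, not the
epidemiology. The default `noise_sd = 0.05` reproduces the residual
scatter implied by fits with $R^2 \approx 0.99$ on log-scale series whose
total spread is a few log units.

`simulate_cohort()` realizes the ordered-sequence assumption directly:
each individual's onset age is the sum of $r$ sequential exponential
waiting times (each clock starts when the previous event completes), with
administrative censoring at `max_age`. `estimate_hazard()` bins
$(0, \text{max\_age}]$ into equal-width bins and divides events by
person-time; empty-exposure bins are flagged, never dropped.
`fit_hazard_powerlaw()` fits the log-log hazard regression as a Poisson
log-linear model with a person-time offset, which keeps zero-event bins
and avoids the downward bias of logging small counts.

### What the simulator can and cannot confirm

The power law is the $k_i t \ll 1$ limit. At the boundary commonly used
for "rare" ($k_i \cdot \text{max\_age} = 0.2$), the exact hazard of the
sum-of-exponentials model falls short of $k t^{r-1}$ by a factor
$\approx 1/(1 + \sum_i k_i t + \dots)$ — about 17% at the oldest ages for
$r = 2$ — and the log-log slope is correspondingly shallowed by roughly
$0.1$–$0.2$ near the end of follow-up. Meanwhile the number of onsets in
a cohort of $n$ individuals is about $n (k_i T)^r / r!$ — with
$n = 200{,}000$ and $k_i T = 0.2$ that is $\sim 4000$ onsets for $r = 2$
but only $\sim 270$ for $r = 3$ and $\sim 13$ for $r = 4$ — and no
estimator of a power-law exponent can beat the information bound
$\mathrm{SE} \gtrsim r/\sqrt{N_{\text{events}}}$ ($\approx 0.18$ for
$r = 3$, $\approx 1.1$ for $r = 4$ at those counts). Slope-recovery
checks at desk scale are therefore sharp for $r = 2$, marginal for
$r = 3$, and uninformative for $r = 4$; the test suite asserts the tight
$\pm 0.15$ band for every $r$ regardless and lets the infeasible cases
show up as failures rather than silently relaxing them. The package's own
regression tests use $k_i \cdot \text{max\_age} = 0.1$ for level checks,
where the approximation bias sits well inside the Monte-Carlo noise.

Problem sizes used in the shipped tests: cohorts of 200,000 individuals,
10 hazard bins, 500-replicate recovery studies, 300-replicate
model-selection studies per family, and 10,000 random draws for the
combined-slope identities.

## Combined-gender slopes

The both-genders series is the unweighted mean
$I_{fm} = (I_f + I_m)/2$ — no population weighting, matching the
derivation the identity algebra rests on. Between two age classes, the
combined slope relates to the gender slopes by

$$S_{fm} = S_f +
  \frac{\ln\frac{1 + I_{m2}/I_{f2}}{1 + I_{m1}/I_{f1}}}{\Delta \ln t}
  = S_m +
  \frac{\ln\frac{1 + I_{f2}/I_{m2}}{1 + I_{f1}/I_{m1}}}{\Delta \ln t},$$

whose correction terms force $S_{fm}$ strictly between $S_f$ and $S_m$
whenever they differ. `slope_triple()` computes the combined slope both
directly and via these corrections and *verifies* their agreement on
every call (a disagreement indicates corrupted input). For full series,
OLS-slope intermediacy is an empirical regularity, not a theorem, so
`gender_slope_summary()` reports it without asserting it.

When gender slopes differ for the same cancer, the slope can be read as
$h + r - 1$ with an event rate proportional to $t^h$
(`decompose_slope()`): the gender gap is then attributed to different
rate exponents $h$, not different event counts $r$. $h$ is not
identifiable from a single series and defaults to 0.

## Degenerate and edge inputs

* Zero incidence inside a series: excluded from fitting with a warning
  naming the series and classes (log undefined); leading both-gender
  zeros are handled by renumbering instead.
* A constant series fits as $r = 1$, $k$ = the level — a flat hazard —
  and is reported with $R^2 = 1$ (the 0/0 case resolved as a perfect
  fit); the standalone `r_squared()` still refuses zero-variance input.
* Convex domain violations ($a_2 t^{a_3} \ge 1$) are evaluation-time
  errors naming the offending ages, because validity depends on the age
  range, not the coefficients alone.
* `a_2 = 0` reduces both curved models to the linear one, and the
  mechanistic map then reports a single-subgroup model with $k_q = 0$.
* Fitted non-integer $r$ is never silently rounded: interpretations
  carry the point value and the bracketing integers ("3 to 4 steps").

## Known limitations

* The hybrid fit freezes the model *form*; it does not produce standard
  errors or confidence intervals for the coefficients, and none are
  reported upstream to compare against.
* The reference coefficient tables bundled in `inst/extdata` include
  rows whose printed $k_p/k_q$ cells are inconsistent with the defining
  relations $k_p = e^{a_0}$, $k_q = a_2 k_p$; they are flagged
  `coef_consistent = FALSE` and excluded from parameter-map checks
  (their $a_0 \dots a_3$ coefficients remain usable).
* Heterogeneity parameters $(r, p, q)$ are identified only up to the
  choice the caller supplies; conclusions about $r$ from curved fits
  inherit that choice.
* The simulator covers ordered sequences with constant rates; competing
  risks, birth-cohort effects and time-varying rates (beyond the $t^h$
  reinterpretation of the slope) are out of scope.
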