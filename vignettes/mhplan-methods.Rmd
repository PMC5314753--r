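---
title: "Modelling mental-health burden, services and avertable burden in conflict-affected populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mental-health burden, services and avertable burden in conflict-affected populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhplan)
```

# The modelling chain

`mhplan` implements a planning chain for mental health services in
conflict-affected populations, with Syria as the parameterised
case-study. Four stages share a common set of age-indexed inputs
(population counts, mortality hazards, prevalence curves for ages
0--100):

1. **Prevalent cases.** Age-standardised prevalence estimates of PTSD
   (12.9%, 95% UI 6.9--22.9) and major depression (7.6%, 95% UI
   5.1--10.9) are applied to the population and partitioned into
   PTSD-only, depression-only and comorbid cases, with 50% of PTSD cases
   comorbid with depression.
2. **Burden.** Years lived with disability (YLD): prevalent cases of
   each severity class times its disability weight, with Monte-Carlo
   propagation of prevalence and disability-weight uncertainty. The DALY
   burden of these disorders is dominated by the YLD component, so no
   years-of-life-lost term is modelled.
3. **Service resources.** An mhGAP-costing-tool style model of visits,
   bed-days, beds and full-time-equivalent (FTE) staff needed to scale
   packages of care from 1% baseline coverage to their target coverages
   over a 15-year horizon, linearly or exponentially.
4. **Avertable burden.** A multi-cohort Markov (illness-death) model
   that propagates six adult age cohorts through healthy/diseased/dead
   states over 15 years and compares treatment scenarios against a
   partial-null (no treatment) comparator.

# Synthetic study population

No public deposit carries the original UN population and GBD mortality
tables, so the package generates a synthetic population with the same
statistical structure, and every stage runs against it offline.

* **Pyramid.** `make_population()` uses an exponentially declining age
  profile (rate 0.028/year of age), a standard stylisation of a young,
  high-fertility population; the female share defaults to 0.493.
  The default total, `2.2e6 / 0.129` (about 17.05 million), is anchored
  so that the 12.9% age-standardised PTSD prevalence yields exactly
  2.2 million prevalent cases. The published case counts are mutually
  inconsistent at the printed prevalences (the depression count implies
  a smaller multiplier), so the PTSD anchor -- the lead figure -- was
  chosen once and kept.
* **Mortality.** A Gompertz--Makeham schedule
  $h(a) = A + B e^{\theta a}$ with defaults $A = 0.0035$,
  $B = 3.2\times10^{-5}$, $\theta = 0.095$, calibrated once so the
  implied life expectancy at birth (68.5 years) falls in the 65--75
  range plausible for the setting. `life_expectancy()` exposes the
  life-table check.
* **Prevalence curves.** `make_prevalence_curve()` shapes prevalence as
  a log-normal density in age with its mode at 25 years (spread 0.75),
  matching the observation that prevalent cases concentrate in
  adolescents and young adults, then rescales so the age-standardised
  value equals the target *exactly* (the rescaling is linear, so the
  identity holds to machine precision). A curve that would be pushed
  above 1 at any age is an error rather than a silent clamp.
* **Uncertainty.** `draw_parameters()` fits a log-normal (rates) or beta
  (proportions) distribution so that its 2.5th/97.5th percentiles match
  the stated 95% interval -- the beta by a two-parameter quantile
  search -- and draws reproducibly from an explicit seed without
  disturbing the caller's RNG stream.

What the generator does **not** emulate: migration and refugee outflow,
sex-specific mortality, calendar-year population projections, and any
real age structure beyond the smooth stylised pyramid. Tests passing on
this fixture therefore validate the *arithmetic and dynamics* of the
pipeline, not the demographic accuracy of any particular projection for
Syria.

# Severity splits and disability weights

The GBD-2010-style severity models carry four classes (asymptomatic,
mild, moderate, severe). Disability weights are the published GBD 2010
values for major depressive disorder (0.159/0.406/0.655 for
mild/moderate/severe) and anxiety disorders (0.030/0.133/0.523), the
latter serving as the PTSD proxy since GBD 2010 carries no
PTSD-specific weights. The class proportions are constrained by the
published moderate-plus-severe shares -- 28% for depression, 30% for
PTSD/anxiety -- which drive treatment eligibility; the split of the
remainder between asymptomatic and mild follows GBD-2010-style
distributions (depression 14.5/57.5/19.7/8.3; anxiety
10.2/59.8/14.8/15.2). All of these load from the YAML configuration at
run time, so a revised severity table can be swapped in without code
changes.

Comorbid cases contribute to both disorders' YLD totals, exactly as
disorder-level burden accounting implies; the GBD micro-simulation that
redistributes comorbid disability is out of scope and no implementable
recipe for it exists, so none is faked.

The Monte-Carlo point estimate of a YLD total is reported as the mean
of the draws (matching spreadsheet-bootstrap practice), with the
deterministic cases-times-weight product also returned; with the
right-skewed prevalence interval the mean sits above the deterministic
product.

# Service-resource model

The resource arithmetic follows the mhGAP costing tool exactly:

* visits = eligible x coverage x proportion receiving x visits/person;
* bed-days = eligible x coverage x percentage use x bed-days/person;
* beds = bed-days / 365 x 1.15 (86% occupancy);
* outpatient FTE = visits x provider share / (consults/day x days/year);
* inpatient FTE = beds / 25 x staff per 25-bed ward.

Eligibility is moderate-severe cases aged 15+, with the perinatal
package eligible population defined as women 15--44 x 11% fertility x
15% perinatal depression x 28% moderate-severe. PTSD-only cases receive
the depression packages of care but never inpatient treatment; comorbid
cases receive depression packages including the inpatient component.

The per-package visit counts, provider shares, consultations per day
and ward staffing are **reconstructed, not transcribed**: the original
values live in an online supplementary table that is not reproduced
here. The reconstruction fixes the free parameters once so that the 1%
baseline year reproduces the published service-contact volumes
(roughly 37,000 primary-care, 78,000 ancillary and 6,000 outpatient
visits and 1,000 bed-days) and the FTE-per-100,000 endpoints (0.3 at
baseline, about 7.6 after scale-up); with those anchors fixed,
everything in between follows from the coverage trajectory. The
defaults are deliberately round, mhGAP-plausible numbers (e.g. basic
psychosocial care: 3 primary-care + 6 ancillary visits; medication
management: 4 + 8; intensive psychosocial: 12% receiving 8 outpatient
visits, 2% using 17 inpatient days).

Two modelling choices differ knowingly from the original exercise.
First, the population is held at its 2015 size (a per-year projected
population is accepted but not defaulted), so final-year service
contacts scale by exactly `target/baseline` from the baseline year;
the published final-year contact volumes embed UN population growth
projections and are therefore *not* reproduced -- the endpoints
asserted in tests are the baseline contacts and the FTE rates, which
are population-normalised. Second, the 15-year horizon is indexed
t = 0 (2015) to t = 14 (2029), treating the "2015--2030" label as
inclusive of a reporting year.

Coverage interpolation is affine for the linear mode and geometric
(`c0 (cT/c0)^(t/14)`) for the exponential mode -- the published account
names the shapes but not the formulas. Both modes agree at both
endpoints by construction; exponential coverage lies below linear
strictly inside the horizon. Beds and FTE are kept unrounded
internally; reports round beds to integers and FTE to one decimal.

# Illness-death engine

The three-state model (healthy S, diseased C, dead D) uses hazards
i (incidence), r (remission), f (excess case mortality) and m
(background mortality). Within a year the hazards are constant, so the
(S, C) subsystem is linear with constant coefficients and is advanced
with the exact matrix exponential; deaths accrue from the exact
within-year person-time integral. Both the exponential and its
integral come from one truncated Taylor series with
scaling-and-squaring, which makes the conservation identity
`E - I = A P` hold to machine precision -- cohort mass S + C + D is
conserved to ~1e-13 relative over long trajectories. A per-step RK4
oracle with 1000 substeps agrees with the closed form to 1e-6 relative
in tests. (A 1000-substep *forward-Euler* scheme is only first-order
accurate and cannot reach 1e-6 at these hazard magnitudes, which is why
the test oracle is RK4.)

Excess mortality is derived from the relative risk as
`f = m (RR - 1)` -- the standard DisMod convention -- with RR = 1.9
for depression-stream cases and 0 for PTSD. Remission defaults are
1.40/year for depression (the published figure; note 52.14/37.7 weeks
is 1.38, the printed rounding is kept) and 0.17/year for PTSD.

`fit_incidence()` back-calculates internally consistent incidence from
a target prevalence curve: a monotone 1-D bisection on i(a) in [0, 10]
per age (tolerance 1e-8, hard cap 200 iterations), clamping at zero
with a diagnostic where prevalence declines faster than remission plus
mortality allow. It returns a classed fit with `coef()`, `fitted()`,
`residuals()`, `predict()` and `plot()` methods; the round-trip
reproduces the target to <1e-6 and recovers a known generating
incidence to <1% relative error.

# Avertable-burden model

Six adult cohorts (15--29, 30--44, 45--59, 60--69, 70--79, 80+) are
modelled from their mid-ages (22, 37, 52, 64.5, 74.5, 85; bands the
source does not state use band midpoints, with 85 for 80+) over 15
years. The model follows the **moderate-severe** caseload: each
stream's initial prevalence is its case prevalence times the
moderate-severe share, and YLDs accrue as within-year diseased
person-time times the conditional moderate-severe disability weight.
Two disorder streams are run -- PTSD-only (remission 0.17, no excess
mortality, anxiety weights) and comorbid depression/PTSD (remission
1.40, RR 1.9, depression weights) -- with depression-only cases folded
into the depression-parameter stream by default
(`include_dep_only = TRUE`), so that all moderate-severe burden is
covered; setting it `FALSE` restricts the model to the two streams
named in the source.

Treatment acts through two channels: remission is raised,
`r' = r (1 + eff_r)`, and disability weight lowered,
`dw' = dw (1 - eff_dw)`. Per-package effective fractions are
`efficacy x target coverage x scale-up coverage(t)` and are combined
across packages with the WHO-CHOICE form `1 - prod(1 - e_k)` (the
published equation is rendered as an image and not transcribable; this
standard form is isolated in `combined_effectiveness()` so it can be
swapped). Scenario scale-up coverage is 0 (partial null), 1% constant
(current), or interpolated 1% to 30% / 100% (target scenarios), linear
or exponential.

The per-package effect sizes are **derived calibration values**, not
published inputs: the source cites them to prior WHO-CHOICE work
without printing them. They were fixed once -- basic psychosocial
0.55/0.40, medication 0.65/0.50, intensive psychosocial 0.80/0.60 on
remission/disability-weight -- from a pre-run feasibility analysis
targeting the published avertable-burden magnitudes under linear
scale-up, and then frozen. With them, the linear-mode runs avert about
8.7% (30% target) and 23.8% (100% target) of the partial-null burden,
inside the published 7--9% and 23--27% bands, and a 3% discount rate
moves the percentages by under two points. Exponential scale-up averts
roughly half as much as linear at the same endpoint -- mean coverage
over the horizon is about half -- which is arithmetically consistent
with the published bands describing the linear headline (the ratio of
the two bands, ~0.30, equals the ratio of the mean linear coverages).

The partial-null scenario is the comparator for "percent averted"
throughout. Discounting, when requested, applies `1/(1+rate)^t` with
year 0 (2015) undiscounted. The scenario engine contains no random
number generation; results are pure functions of the configuration.

# Numerical choices and problem sizes

* Ages are integer single years 0--100, with 100 a closed terminal age;
  cohort trajectories that pass 100 reuse the terminal rates.
  Non-integer mid-ages interpolate rate schedules linearly.
* Case counts, beds and FTE are real-valued internally; rounding is a
  reporting concern only.
* The bisection bound of 10/year for incidence comfortably exceeds any
  epidemiologically plausible value; hitting it is an error, not a clamp.
* Default Monte-Carlo sizes: 2,000 draws in the pipeline's burden stage
  (percentile noise well under the interval widths), 1e5 draws where
  interval recovery itself is being verified. Default seed 20150101.
* A full pipeline run (synthetic inputs through all scenarios) takes a
  few seconds on one core; the test suite runs in a few seconds.

# Known limitations

* Only depression and PTSD (plus perinatal depression in the service
  layer) are modelled; other mental, neurological and substance-use
  burdens are outside scope, as are monetary costing, training and
  supervision overheads, and non-clinical roles.
* The comorbidity partition uses a single scalar (50% of PTSD cases)
  applied age-by-age and clamped at the depression caseload.
* Service volumes assume the care-package composition and staffing
  shares are constant over the horizon.
* The effect-size calibration makes the avertable-burden *levels*
  reproducible by construction at the calibration points; the model's
  scientific content there is in the scenario contrasts (coverage
  monotonicity, linear-vs-exponential dominance, discount robustness),
  which are asserted independently of the calibration.
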