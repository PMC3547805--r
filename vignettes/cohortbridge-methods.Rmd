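---
title: "Correcting register-based mortality trends for unlinked deaths and coding changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting register-based mortality trends for unlinked deaths and coding changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A census-based mortality cohort follows every person enumerated at a census
until death, emigration or an administrative end of follow-up, with deaths
ascertained by record linkage to the national death registry. Two artefacts
distort the mortality trends such a cohort produces.

First, a small share of death certificates cannot be linked to any census
record (incomplete enumeration, undocumented migration, data errors). An
unlinked death removes an event from the numerator *and* leaves its person
accruing person-time in the denominator, so absolute rates are biased
downwards — increasingly so with distance from the census, and most visibly
in the oldest age groups where over half of all deaths occur. Relative
mortality (hazard ratios) is affected only when linkage failure is
differential with respect to the exposure under study.

Second, a change in cause-of-death coding policy — here, a switch at
1 January 1995 from an ICD-8 coder that gave priority to certain mentioned
causes (accident/poisoning/trauma, influenza, cancer) to strict ICD-10
underlying-cause coding — produces a sudden step in cause-specific rates
between two adjacent calendar years that has nothing to do with mortality
itself. Cancers with long survival are most affected: before the change, a
cancer mentioned on the certificate of a person who died of something else
often *became* the official cause.

`cohortbridge` implements the correction pipeline for both problems and a
synthetic data generator with retained ground truth on which the pipeline is
validated end to end.

## The synthetic generator

### Census waves

`generate_census()` draws independent person records with configurable
categorical marginals (sex, canton → region and language region, nationality,
marital status, education, religion, urbanization, household type) and a
ten-group age distribution; defaults are styled after the census-2000
population margins of the cohort literature (e.g. 79%/21% Swiss/non-Swiss,
ages strongly concentrated under 65). Children under 15 are forced to
marital status `single` and education `not_applicable`. Two waves are
simulated by default — 5 December 1990 followed to 4 December 2000, and
5 December 2000 followed to 31 December 2007 — so that each death year maps
to exactly one cohort and no person-time is double counted. The waves are
independent draws: we do not model the same individuals appearing in both
censuses, which is immaterial for rate and hazard-ratio computations done
within waves.

### Events

`simulate_followup()` uses competing exponential clocks per cause,
piecewise-constant over attained-age bands and calendar years
(`rate * exp(slope * (year - 2000))` for the optional log-linear trends).
This matches the rate-based analyses downstream exactly — the
piecewise-exponential likelihood used for hazard ratios is then the true
likelihood — and gives closed forms for tests. Proportional covariate
effects (default: tertiary education HR 0.9, compulsory 1.05, single 1.25,
widowed 1.10, divorced 1.15, non-Swiss 0.95 on all death causes) provide a
known truth for the hazard-ratio models. Emigration is an additional
competing risk with age-band-specific rates.

Each death carries its underlying cause plus possible additional mentions:
cause `c` is mentioned on a death whose underlying cause is different with
probability `m(c, sex, age band)`. The era-appropriate coder
(`assign_official_cause()`) then sets the official cause: before the switch
date, a mentioned cause in the highest-priority group (external > influenza
> cancer) displaces a lower-priority underlying cause (the underlying cause
is kept when it is itself in the top mentioned group); from 1995 onward the
official cause is the underlying cause.

This mechanism makes the coding step *emerge* with an analytically known
size. For a priority cause `c` with mention probability `m`, the pre-switch
official rate is `lambda_c + m * lambda_np` (`lambda_np` = total hazard of
lower-priority causes), the post-switch official rate is `lambda_c`, so the
multiplication factor is

```
f = lambda_c / (lambda_c + m * lambda_np)
```

(`coding_step_factor()`; `mention_prob_for_factor()` inverts it). The
default configuration calibrates breast-cancer mentions in women and
prostate-cancer mentions in men so that the implied 85+ factors are 0.80 and
0.84 with near-unity values at 75–84 — the qualitative pattern reported for
the Swiss coding change. The formula is exact when at most one priority
cause has a positive mention probability per sex, which holds for all
shipped configurations.

Certificate identifying fields evolve between census and death: marital
status moves along the plausible-transition table at a configurable rate and
the canton of residence changes with probability 0.10, so that even
perfectly linked records disagree with the census at realistic levels.

### Unlinkage

`degrade_to_registry()` turns each death into exactly one registry record
and draws its linkage failure per stratum of (age group at death, sex,
nationality, marital status). The default table is built multiplicatively
from an age-band base (high in children and young adults, ~3–4% in the
elderly) with modifiers for sex (men 1.08), nationality (non-Swiss 2.3 vs
Swiss 0.88) and marital status (singles 1.4), echoing the published
characteristics of unlinked deaths; at the default study conditions the
overall unlinked share of deaths lands near 5%. Unlinked certificates are
additionally perturbed — the assumed data-error mechanism behind linkage
failure, which the source material does not characterise beyond its
marginals: birth date exact with probability 0.5, within ±92 days with 0.4,
within ±366 days with 0.1 (this mixture is what makes step-1 date agreement
high and step-2 agreement near zero); canton replaced with probability 0.5;
marital status replaced with probability 0.15. The true person id is always
retained in `truth_person_id`, which analytic modules are contractually
forbidden to read — only evaluation code may.

## The two-step allocation

Unlinked certificates are processed in a fixed order (death date, then
certificate id; the source procedure is silent on order, and
person-exclusivity makes order matter, so determinism requires fixing one).
For each certificate:

* **Step 1**: candidates must match sex, canton and nationality exactly,
  birth date within 92 days ("maximally 3 months" read as a calendar-safe
  day bound), and census→certificate marital status must be identical or a
  plausible change (identity pairs plus single→married,
  married→widowed/divorced, divorced→married, widowed→married — the legally
  possible transitions).
* **Step 2** (only if step 1 finds nobody): sex and major region equal,
  birth date within 366 days.

Persons already carrying a linked death, consumed by an earlier allocation,
or emigrated before the certificate's death date are ineligible, and
sex-specific causes exclude the incompatible sex entirely. Ties are broken
uniformly at random by a seeded generator whose seed is recorded in the
result. Summary percentages follow the printed conventions of linkage
reports: one decimal at or above 1%, two significant figures below, and the
allocated share reported as 100 minus its rounded complement so the pair is
consistent (99.74 / 0.26).

## Person-time and rates

Exposure is counted in whole days, each day labelled by its end date: the
day ending on date `d` belongs to calendar year `year(d)` and to the
attained age held on `d` (ages increment on birthdays; a 29 February
birthday increments on 1 March in common years). Intervals are split at
calendar year-ends and at the birthdays where the attained-age group
changes, which makes person-time conservation exact in integer days under
any stratification — a property the tests assert against an independent
day-by-day enumeration oracle. Attained age (not age at census) is used for
rate strata; an 85+ series over 17 years is meaningless otherwise. Person
years are days / 365.25. Default age groups are 0–4, 5–14, …, 75–84, 85+,
with reporting focused on the two oldest groups.

Rates are deaths per 100,000 person-years per (year, sex, age group, cause).
Three variants matter: *excluding* unlinked deaths (persons whose
certificate never linked stay under observation to the end of the window —
exactly the bias mechanism), *including* allocated deaths (the allocated
person's exposure ends at the certificate's death date), and *reference*
rates (all certificates divided by the midyear population; in the synthetic
setting the midyear population is the exact count of persons alive and
present on 1 July, computed from generator truth). `relative_difference()`
summarises `(cohort − reference) / reference` per year with mean/min/max
over years; strata with a zero reference rate are flagged undefined rather
than propagated.

## The coding-change trend model

Annual death counts `D_t` with person-time `T_t` for one (cause, sex, age
group) stratum are modelled as

```
D_t ~ Poisson(mu_t),  log mu_t = log T_t + b0 + f(t) + g * 1(t >= 1995)
```

with `f` a restricted cubic spline in calendar year. The basis is Harrell's
truncated-power parameterisation (one linear column plus `k − 2` nonlinear
columns scaled by the squared knot range, linear beyond the boundary knots);
with no spline implementation among the package's dependencies it is
implemented directly and tested for boundary linearity and translation
invariance. The knots 1990, 1995, 2000, 2004 are used exactly as printed in
the source material even though they are not literally equally spaced:
printed locations beat adjectives. The step indicator is `1(year >= 1995)`
on annual aggregates, since the policy changed on 1 January. Each (cause,
sex, age group) stratum is fitted separately, as the published tables
present them.

Fitting is by `stats::glm` (IRLS to a relative deviance change below 1e-11,
at most 100 iterations); the tests verify the fitter against an independent
multi-start quasi-Newton maximisation of the hand-written likelihood to
1e-6. All counts zero is an error; a regime with no events flags the fit as
separated rather than reporting a meaningless step. `exp(g)` with its Wald
95% CI on the log scale is the multiplication factor; percent reductions
round half away from zero to the integer (0.843 → 16%, 0.792 → 21%).
`adjusted_rate_series()` forces the step to its post-change value for all
years, giving pre-1995 rates as if the new policy had always applied, with
delta-method intervals on the linear predictor.

## Hazard ratios with and without unlinked deaths

Hazard ratios for education (reference: secondary), marital status
(married) and nationality (Swiss) are estimated by piecewise-exponential
Poisson likelihood on calendar-year × age-group slices, adjusted by default
for language region, religion, urbanization, calendar year (categorical, as
the published footnotes list it), age group, sex and the other two
exposures. We use the piecewise-exponential form rather than Cox partial
likelihood deliberately: it is self-implemented and oracle-testable
(two-group instances reduce to the exponential closed form, which the tests
check to 1e-8), and it is *exactly* the generator's likelihood, since the
generator simulates piecewise-constant hazards. Under proportional hazards
with a flexible enough time axis the two estimators agree closely; this
deviation from the Cox models of the source analysis is a documented design
choice. Slices under attained age 15 are excluded from education models
(education is undefined for children), and a person's education is the
census value — certificates do not record it, so allocated deaths inherit
the allocated person's education.

`compare_with_without()` fits each model twice — excluding unlinked deaths
(their persons censored administratively at the window end) and including
the allocated deaths — and tabulates both columns with absolute
differences. The bookkeeping identity (event counts differ by exactly the
allocations per level) is asserted in tests.

## Evaluation studies and their sizing

Three pre-specified experiments exercise the pipeline against known truth;
they are shipped as package functions so that tests and the acceptance
script run the same code.

**Coding-step recovery** (`coding_step_study()`). A male cohort aged 75–94
at census, 50,000 persons per wave, a single flat hazard stratum (all-cancer
0.033, cardiovascular 0.045, other 0.032, suicide 0.0005 per person-year —
stylised elderly male levels), no calendar trend, and a cancer-mention
probability calibrated so the official all-cancer rate steps by exactly
0.85 at 1995. Two aspects of this design were fixed by pre-hoc analysis.
*Power*: with the 1995 knot sitting on the step, the spline absorbs much of
the contrast; a Fisher-information calculation shows a female 85+ cohort of
the same size would estimate the factor with a standard error too large for
a mean absolute error below 0.03, while the male 75+ all-cancer design
predicts a factor-scale standard error near 0.033 (predicted MAE ≈ 0.026).
*Model congruence*: the cohort must form a single hazard stratum. An
earlier variant pooling two age bands with different hazard levels made the
pooled rate drift with the age mix and jump at the wave changeover — a
composition discontinuity the smooth spline cannot represent, so lack of
fit leaked into the step estimate and the analytic factor was no longer
the exact estimand of the fitted model. With one stratum the official rate
is exactly piecewise constant and the factor is exactly identified. The
evaluation criterion is 95% CI coverage of the truth across 200 replicates
and the mean absolute error of the point estimate.

**Rate correction** (`rate_correction_study()`). One census wave of 50,000
persons at the default all-age conditions (~5% unlinked), comparing 85+
all-cause rates against generator-truth reference rates: uncorrected rates
must undershoot (strictly negative mean relative difference) and corrected
rates must track the reference within 2%.

**Hazard-ratio robustness** (`hr_robustness_study()`). An elderly cohort
(75–95 at the 1990 census, 30,000 persons) under the default unlinkage
model, in which education never enters the unlinkage probabilities
(non-differential) while nationality multiplies them by 2.3 (strongly
differential). The education comparison must move by less than 0.03 per
level; the nationality comparison must exceed that band — the two halves of
the robustness argument, demonstrated on the same run.

Problem sizes (50,000 per wave; 200 replicates; 30,000 for the hazard
study) are the package's fixed evaluation conditions, chosen by the power
considerations above.

## Numerical choices and degenerate inputs

* Ties at the end of follow-up resolve death > emigration > administrative.
* Same seed ⇒ identical output everywhere; each pipeline stage derives its
  seed deterministically from the base seed, and tie-break seeds are stored
  in the allocation result.
* GLM convergence: relative deviance change < 1e-11 (trend model) and
  < 1e-12 (hazard models), 100 iterations; non-convergence is flagged.
* Zero unlinked certificates: allocation returns empty tables and the
  summary flags itself degenerate instead of dividing by zero. Empty
  agreement strata are flagged `undefined`.
* A stratum with deaths but no person-time (or missing from the midyear
  table) is an error, not a silent `Inf`.
* Constant adjusters are dropped from hazard-model designs (a single-sex
  cohort would otherwise break the factor contrasts).

## Limitations

* The generator's marginals are independent across covariates (apart from
  the age restrictions on marital status and education), so real-world
  correlations — education with age, nationality with region — are absent;
  passing tests show the pipeline's correctness under its stated model, not
  calibration to any real population.
* Certificate perturbation is a stated assumption, not a reconstruction of
  why real records fail linkage; the true-match rate of the allocation is
  reported on synthetic data but has no real-world analogue to be checked
  against.
* Hazard ratios use piecewise-exponential, not Cox, estimation (see above).
* Real Swiss rates, canton sizes and ICD code mappings are out of scope; no
  attempt is made to reproduce published Swiss tables beyond their in-text
  arithmetic.
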