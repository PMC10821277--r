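---
title: "Atypical mitotic figures as prognostic markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atypical mitotic figures as prognostic markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfmct)
```

## The problem

Canine cutaneous mast cell tumors (ccMCT) are among the most common skin
tumors of dogs, and most are cured by surgery alone. Histologic
prognostication hinges on proliferation: the mitotic count (MC), the
number of mitotic figures (MFs) in a 2.37 mm2 hotspot region
(approximately 10 high-power fields), is both a standalone prognostic
test and a component of the 2011 two-tier grading scheme. Mitosis in
neoplastic cells can, however, go visibly wrong: atypical mitotic
figures (AMFs) — bipolar size asymmetry, spindle multipolarity,
chromosome or fragment lagging, chromosome bridging, dispersed
chromatin and more complex forms — are the morphologic trace of
chromosome segregation errors, and their frequency is a distinct signal
from the frequency of mitosis itself. This package implements the full
evaluation pipeline for AMF-based prognostic tests in a ccMCT survival
cohort: per-case marker statistics, threshold classifiers, diagnostic
accuracy with exact intervals, ROC/AUC, Kaplan-Meier and Cox analysis,
a calibrated synthetic cohort generator, and a frozen reference
fixture.

## Marker statistics

Four quantitative markers are computed per case, all over the same
2.37 mm2 region:

* **MC** — all MFs, normal and atypical;
* **AMF count** — atypical MFs only;
* **adjusted AMF:MF ratio** — `max(AMF - 1, 0) / MC`, and 0 when
  MC = 0. The subtract-one rule exists because a single AMF in a tumor
  with 0–1 normal MFs would otherwise produce a ratio of 50% or 100%;
  such cases occur (nine in the reference fixture) and have good
  outcomes, so one AMF is never allowed to score. A consequence worth
  knowing: a case can only be ratio-positive with at least two AMFs.
* **multipolar AMF count** — the subtype with supernumerary spindle
  poles, easy to recognize and biologically severe.

The two-tier grade is high if MC ≥ 7, multinucleated cells ≥ 3,
bizarre nuclei ≥ 3 (each per 10 HPF), or karyomegaly is present; the
MC criterion is evaluated first and the basis of the call is recorded.

The default classifiers are AMF count ≥ 3, adjusted ratio > 7.5%
(strict: exactly 7.5% is negative), MC ≥ 6, presence of any multipolar
AMF, and high grade. Counts use inclusive cuts, the ratio a strict
one; these boundary semantics are fixed in `default_rules()` but every
cutpoint is a plain parameter of `threshold_rule()`, because the
evidence behind any specific cut in a 96-case series is thin and
screening alternative cuts is a legitimate use of the package. The
combination rule `combined_mc_ratio()` is a logical AND of the MC and
ratio classifiers: its positives are a subset of the MC positives, so
it can only remove false positives (mitotically active tumors whose
figures are overwhelmingly normal), never add them.

Thresholds are defined for the 2.37 mm2 region. Counts from a
different region area are *not* rescaled — the cuts were never
validated at other areas — the package warns instead.

## Accuracy machinery

`confusion()` cross-classifies a rule against either tumor-related
death (primary outcome, any time during follow-up) or all-cause death
within 12 months (the minimum follow-up, so the binary outcome is
well-defined for every included case). Sensitivity, specificity and
positive predictive value carry two-sided Clopper–Pearson exact
intervals computed from the beta-quantile closed form; exact intervals
were chosen because the degenerate cells that occur here (0 false
positives in 83, 83/83 true negatives) break normal approximations,
and for x = n the lower bound has the closed form `(alpha/2)^(1/n)`.
A metric with a zero denominator is reported as undefined, never as 0.

The AUC is the pairwise concordance probability (Mann–Whitney
convention, ties count one half), computed from average ranks; the ROC
curve is built by enumerating thresholds at midpoints between distinct
scores, and its trapezoidal integral equals the concordance exactly —
the test suite holds the two routes to within 1e-12, with a
brute-force pair count as the independent oracle. The AUC interval
uses the DeLong placement-value variance, truncated to [0, 1]. This is
a convention choice, not a reproduction claim: the interval method
behind published AUC CIs for this problem is unnamed.

## Survival machinery

`build_survival()` encodes the two survival definitions:
tumor-specific (tumor-related death is the event; other-cause deaths
and losses to follow-up are censored at their times) and overall (any
death is the event). Kaplan–Meier estimation is the standard
product-limit estimator; with no censoring it equals the empirical
survivor function exactly, the median is the smallest event time with
S(t) ≤ 0.5 and is reported explicitly as "not reached" when the curve
never gets there — never as a number.

The Cox model is univariate (a single classifier indicator), maximized
by Newton–Raphson on the partial likelihood with **Efron's tie
correction** — ties are ubiquitous here because follow-up is recorded
in months. Iteration starts at 0 and stops when the absolute score
falls below 1e-9 or the step below 1e-10 (at most 50 iterations); the
Wald interval uses the fixed quantile 1.959964. Monotone-likelihood
configurations — a binary group with zero events, or a coefficient
walking past ±20 — are flagged non-convergent and no estimate is
reported; this actually happens in small cohorts when a highly
specific marker (multipolar presence) captures only deaths. The test
suite requires agreement with the `survival` package (the oracle, not
the implementation) to 1e-6 on random tied datasets.

## The synthetic cohort generator

The generator (`generator_params()`, `generate_cohort()`) emulates the
structure the analysis assumes: a latent benign/aggressive dichotomy;
a negative-binomial MC per class (hotspot counts are overdispersed —
the observed range runs from 0 to triple digits while most low-grade
tumors have MC ≤ 5); a per-case atypia probability drawn from a
class-specific beta, making the AMF count beta-binomial given the MC;
a binomial multipolar count within the AMFs; competing exponential
tumor-related and other-cause death times; administrative censoring
uniform on (0, H); and the inclusion rule — a case censored alive
before 12 months is redrawn (bounded at 1000 attempts), as such
patients would have been excluded from the study.

Default calibration, chosen once against the published cohort
composition and then frozen: 96 cases; aggressive share 18/96 (the
high-grade fraction); MC ~ NB(mu 2.4, size 1.2) benign and
NB(mu 25, size 1.5) aggressive, giving an expected MF total near 640;
atypia Beta(0.6, 9) benign and Beta(3, 12) aggressive, for an expected
AMF total near 100 (≈ 16% of MFs); multipolar probability 0.02/0.15;
monthly tumor-death hazards 0.0007/0.03 and other-cause 0.003; H = 60
months. Under these values the closed form gives a tumor-death
probability of 0.138 per included case (~13.3 deaths per cohort) and a
61% aggressive-class mortality, matching 11 deaths among 18 high-grade
cases. One deliberate mismatch: constant (exponential) hazards cannot
simultaneously produce 61% class mortality over this censoring pattern
and a marker-positive median survival under 10 months; the calibration
favors the mortality fractions, so generated survival curves fall more
slowly than the published ones. Grading covariates (multinucleation,
bizarre nuclei, karyomegaly) are not simulated — generated high grade
is driven by the MC criterion alone.

`closed_form_operating_point()` is the oracle for what the generator
should produce: because counts and survival are independent given the
class, the expected sensitivity of a count rule is the class-mixture
of exact mass-function tail sums with weights proportional to class
probability times class death probability (and analogously for
specificity via inclusion-minus-death weights). The acceptance suite
drives empirical pooled operating points over 200 replicate cohorts to
within 3 Monte-Carlo standard errors of this closed form, and
recovers a true class hazard ratio of 4 from 25 replicate two-class
cohorts of 800.

What passing these tests shows — and does not. They show the
estimators are correct for data with this structure: overdispersed
counts, beta-binomial atypia, proportional exponential hazards,
uninformative censoring. Real cohorts violate several of these
(hazards are not constant, censoring may be informative, atypia may
correlate with survival within class, a hotspot is a chosen region,
not a random one), so the tests validate the arithmetic of the
pipeline, not the biology of any particular threshold.

## The reference fixture

`paper_fixture()` is a deterministic 96-case cohort reconstructed from
published aggregates: every threshold-level cell (16/11/10/8 positives
with their death splits, the 650/103 MF totals, the 18-case high-grade
tier with its basis composition, the 0–15 AMF and 0–37.5% ratio
ranges, the nested structure of AMF positives inside MC positives)
is fixed by those aggregates; the free cells — individual mitotic
counts among threshold-negative cases — are frozen values chosen to
hit the totals while keeping every such case below all thresholds.
Two of the three classifier-negative tumor deaths are low grade and
the third carries karyomegaly, the minimal assignment consistent with
the published tier-by-outcome counts. Its follow-up times are
synthetic placeholders (deaths cluster within the first year,
survivors are followed ≥ 12 months); the source aggregates publish no
per-case survival times, so KM medians, hazard ratios, AUCs and CI
endpoints computed on the fixture characterize the fixture only. The
rendered report says this in its caveat section. The same table ships
as `inst/extdata/paper_fixture_cohort.csv` and a test pins the file to
the in-code construction.

## Numerical and formatting conventions

Percentages render to one decimal with round-half-up, AUCs to three
decimals; a specificity of 77/83 therefore prints as 92.8%, one tick
from a published 92.7% produced by truncation — comparisons in the
tests are on the numeric values at printed precision, not on strings.
Undefined quantities propagate as `NA` internally and render as
"undefined". All randomness flows through a single seed per generated
cohort via a private RNG stream that leaves the caller's `.Random.seed`
untouched. Problem sizes in the shipped studies — 200 replicate
96-case cohorts for operating points, 25 replicates of 800 for hazard
recovery, 1000 score sets for the AUC equivalence, exhaustive
Clopper–Pearson enumeration to n = 12 — were chosen to put Monte-Carlo
error well below the tolerances being tested while keeping each run in
seconds.

## Known limitations

* The fixture constrains marginal and threshold-level cells, not the
  full joint distribution of (MC, AMF) among positives; quantities that
  depend on the joint distribution (AUCs above the threshold level)
  are not comparable to published values and are excluded from
  acceptance checks.
* The generator's exponential hazards understate early mortality among
  aggressive tumors (see above).
* AMF subtypes are not weighted; the multipolar-presence rule is the
  only subtype-specific test, mirroring current practice where subtype
  weighting remains an open research question.
* Cutpoint selection itself (scatter-plot inspection in the source
  study) is not re-implemented; cuts enter as parameters.
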