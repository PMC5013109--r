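---
title: "Validating and recalibrating a 6-month mortality risk score for a patient subgroup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and recalibrating a 6-month mortality risk score for a patient subgroup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(graceval)
```

## The problem

Nomogram-based risk scores such as the GRACE score convert a handful of
admission covariates — age, heart rate, systolic blood pressure, creatinine,
a heart-failure proxy, cardiac arrest, ST-segment deviation, elevated
cardiac markers — into a predicted probability of death within six months of
an acute coronary syndrome (ACS). Treatment guidelines key off the predicted
risk bands (low below 3%, moderate 3–6%, high above 6%), so a score that is
well calibrated *on average* but systematically under-predicts for a
subgroup will deny that subgroup guideline-directed early treatment.

Chronic obstructive pulmonary disease (COPD) is the motivating subgroup:
COPD is common among ACS admissions (on the order of 12% in UK registry
populations) and carries excess mortality that the original score inputs do
not capture. `graceval` implements the standard assessment and the standard
fixes:

1. quantify subgroup miscalibration as a Mantel–Haenszel (M-H) risk ratio
   for observed death, pooled over deciles of predicted risk (so the
   comparison is conditional on what the score already predicts);
2. respecify the score as a logistic regression on the same inputs, with or
   without smoking history or the COPD indicator, fitted to the cohort at
   hand;
3. recalibrate multiplicatively: scale the subgroup's predicted risks by
   the adjusted risk ratio estimated in step 1;
4. judge the variants by C-statistic (with DeLong paired comparisons),
   Hosmer–Lemeshow calibration, continuous net reclassification improvement
   (NRI), risk-band reclassification tables and deaths-by-decile
   stratification profiles.

Everything is driven by `grace_validate()`, which returns a fitted-object
style result with `print`, `summary`, `coef`, `predict`, `plot` and
`simulate` methods.

## Cohort model and eligibility

A cohort is a flat table with one row per admission (see `read_cohort()` for
the column contract). Records are excluded, in a fixed order mirroring the
usual registry flow, when they lack (1) a patient identifier, (2) the
obstructive-airway-disease (OAD) indicator, (3) smoking history, or (4)
6-month vital status; each record is counted under the first reason that
applies, so the exclusion log reconciles exactly with the input count.
COPD is derived, not recorded: a patient is flagged when the OAD indicator
is positive *and* they are an ex- or current smoker — an algorithm of the
kind validated against primary-care records for UK ACS registries. A
consequence worth remembering is that never-smokers are never COPD by
construction.

Missing *score inputs* do not exclude a record up front. Each analysis step
is complete-case on the variables it needs and reports its own drop count.
Because the nomogram and every refit model need exactly the same eight
inputs (smoking and the OAD flag are complete after the eligibility step),
all five model variants end up evaluated on one common record set, which is
what makes the paired C-statistic and NRI comparisons valid. Whether
registries drop such records listwise or per-model is rarely stated in
published analyses; per-step complete case is this package's documented
choice, and the drop count appears in every report.

## Scoring engine

The nomogram is table-driven (`nomogram()`, `read_nomogram()`): continuous
variables map to points through a step function over breakpoint intervals
(published nomograms tabulate ranges, not slopes; a linear-interpolation
mode exists behind an argument but is off by default), boolean variables
contribute fixed points, and the total score maps to risk by linear
interpolation between ordered anchors. Out-of-range values clamp to the
terminal intervals/anchors — nomograms are silent about out-of-range
covariates, so clamping is a documented convention here. In-hospital
diuretic prescription stands in for the heart-failure (Killip) term, the
"mini" form of the score used where Killip class is not recorded.

Band boundaries are visible configuration (`risk_bands()`): low is
`[0, 0.03)`, moderate `[0.03, 0.06]`, high `(0.06, 1]`. Published usage
prints "<3%", "3–6%", ">6%" without stating exact-boundary membership, so
the half-open convention is a package decision, kept in one place.

The table shipped in `inst/extdata/` is a *synthetic* GRACE-style nomogram
with a realistic point structure and a monotone score-to-risk curve. It is
not a verified transcription of any published nomogram; every correctness
test in the package runs against small purpose-built nomograms, so nothing
depends on the shipped values. For substantive use, transcribe the
published table you trust into the JSON/YAML format and load it with
`read_nomogram()`.

## The Mantel–Haenszel comparison

Predicted risks for the pooled cohort (both groups together, so strata are
common) are cut into ten equal-count bins by rank, ties broken by stable
input order. Per decile $k$ the 2×2 counts are $a_k$ deaths among $n_{1k}$
subgroup members and $b_k$ deaths among $n_{0k}$ others, $N_k = n_{1k} +
n_{0k}$, and

$$\widehat{RR}_{MH} \;=\; \frac{\sum_k a_k n_{0k} / N_k}{\sum_k b_k n_{1k} / N_k},$$

with a 95% interval from the Greenland–Robins variance of $\log RR$:

$$\widehat{\mathrm{var}}(\log \widehat{RR}_{MH}) =
\frac{\sum_k \left[ (a_k + b_k)\, n_{1k} n_{0k} / N_k^2 - a_k b_k / N_k \right]}
     {\left(\sum_k a_k n_{0k}/N_k\right)\left(\sum_k b_k n_{1k}/N_k\right)}.$$

Strata where either group is empty contribute zero to both sums and are
dropped with a reported count. A single stratum reduces exactly to the
crude risk ratio, which the tests exploit as an oracle. The same machinery
serves any binary subgroup (`subgroup_comparison()`), e.g. diabetes as a
comparator condition.

## Respecification and recalibration

`build_design()` enters the continuous inputs linearly after standardising
with fixed reference constants (`grace_standardisation()`): age centred at
70 years, scaled by 15; heart rate (80, 22) beats/min; systolic pressure
(140, 29) mm Hg; and log-creatinine centred at log(100 µmol/L), scaled by
0.5 — creatinine is a right-skewed laboratory value, so it enters on the
log scale. Fixed constants (rather than per-sample standardisation) keep
coefficients comparable across cohorts and make the synthetic generator's
coefficients directly recoverable by refitting. Smoking enters as two
indicators (ex, current; never as reference), COPD as one indicator.
Fitting is maximum likelihood via iteratively reweighted least squares
(`stats::glm`), with deviance tolerance 1e-8, at most 100 iterations, rank
deficiency reported as an error, and separation flagged when any
standardised-scale coefficient passes 15 in magnitude — beyond that the
fitted probabilities have saturated and the MLE is drifting to infinity.
`bootstrap_fit()` resamples whole records with replacement (patient-level
data) and summarises replicate coefficients for internal validation.

Multiplicative recalibration (`recalibrate()`) scales the subgroup's
predicted risks by a factor $f$ — either supplied (e.g. the headline-style
rounded 1.3) or estimated from the data as the decile-adjusted M-H RR under
the model being corrected — and caps at 1. The cap never binds at
clinically relevant risks but keeps the operation total. Both the exact and
the 1-decimal-rounded factor are carried in the report, since published
practice tends to quote the rounded rule. Two structural facts follow from
arithmetic alone and are pinned by tests: with 3%/6% band edges, any
$f < 2$ makes low→high moves impossible ($0.03 f < 0.06$), and any
$f \ge 1$ never moves a record down a band.

## Metrics

* **C-statistic**: Mann–Whitney construction (ties count one half),
  computed from midranks in $O(n \log n)$ and checked against exhaustive
  pair counting.
* **Paired comparison**: DeLong's asymptotic test from the structural
  components of the two curves on the same records; the variance of the
  difference uses the paired covariance, so rank-identical predictions give
  a degenerate contrast, reported as difference 0, p = 1.
* **Hosmer–Lemeshow**: equal-count groups of predicted risk (default
  $g = 10$), $\sum_g (O_g - E_g)^2 / (n_g \bar\pi_g (1 - \bar\pi_g))$
  against $\chi^2_{g-2}$. The $g-2$ convention presumes the predictions
  were fitted to the sample; it is applied to every model here for
  comparability and noted in the output. For externally supplied
  predictions the statistic is stochastically closer to $\chi^2_g$, a
  distinction the test suite respects by simulating fitted models.
* **Continuous NRI**: $[P(\uparrow|e) - P(\downarrow|e)] +
  [P(\downarrow|\bar e) - P(\uparrow|\bar e)]$ where up/down means any
  change in predicted risk; exact ties count as neither (no epsilon band —
  a documented choice, since tie handling is rarely stated in applied
  reports). The z statistic uses the multinomial variance of the two net
  proportions.

## The synthetic cohort generator

Real ACS registry data are not redistributable, so the package carries a
generator (`generator_config()`, `generate_cohort()`) whose defaults
emulate a large UK-style registry population: COPD prevalence 12.2%;
group-conditional age-band mixes (COPD patients older on average); heart
rate 80.2 ± 21.9 vs 87.2 ± 23.7 beats/min; systolic pressure 139.9 ± 28.6
vs 138.2 ± 29.0 mm Hg; log-normal creatinine moment-matched to 101 ± 56.6
vs 103.4 ± 58.3 µmol/L; in-hospital diuretic use 22.0% vs 32.5%; ST
deviation 60.7% vs 55.3%; elevated markers ~92% in both; smoking mixes with
COPD patients drawn from ex/current only (the identification rule makes
that a logical necessity, and the OAD flag is set jointly so the rule
round-trips). Cardiac-arrest prevalence is a 5% placeholder — registry
tables rarely report it. Deaths are drawn from a logistic model on the
standardised covariates with a COPD log-odds offset (default δ = 0.5) and a
deliberately smaller diabetes offset (0.13) so the comparator-subgroup
ordering is realistic. The intercept default (−3.23) was tuned once,
numerically, so overall 6-month mortality sits near 12%, between the
group-level rates a UK registry would show; it is a documented constant,
not a fitted quantity.

What the generator does *not* emulate: joint covariate correlations beyond
the group-conditional marginals, informative (MNAR) missingness
(`inject_missingness()` is MCAR only), calendar trends in mortality, and —
important for interpreting the recalibration experiments — any dependence
of the subgroup effect on baseline risk. Real cohorts show the subgroup's
conditional risk ratio attenuating toward 1 in the highest-risk deciles
(risks saturate); a single log-odds offset keeps it roughly constant.
Consequently, on generated cohorts the self-estimated multiplicative
recalibration moves the decile-adjusted RR most of the way back toward
unity but settles slightly above it: the open-ended top decile carries
about half the M-H weight, and within it the rescaled subgroup predictions
are structurally right-shifted relative to stratum-mates. Passing tests on
generated data therefore demonstrate the estimators and the machinery, not
that a constant multiplier fully restores calibration for every possible
excess-risk structure.

## Problem sizes and seeds

The test suite and the acceptance script run the recovery experiments at
50,000 records — large enough that coefficient recovery within ±3 standard
errors and the decile-level calibration checks are sharp, small enough to
run in seconds — with bootstrap validation at 100 replicates and smaller
cohorts (2,000–12,000) for structural checks. All randomness flows through
explicit integer seeds; `generate_cohort()` is byte-reproducible given
`config$seed`.

## Worked run

```{r, fig.width = 6, fig.height = 4}
cohort <- generate_cohort(generator_config(n = 20000, seed = 42))
fit <- grace_validate(cohort, seed = 42)
fit
plot(fit)
```

The five rows mirror the usual reporting layout: the nomogram score, the
nomogram with the subgroup's risks multiplied by the estimated factor, the
cohort-refit score, and the refits adding smoking or COPD. On generated
cohorts with a positive COPD offset the base rows show an adjusted RR well
above 1, the ×f and +COPD rows collapse it toward 1, and the +smoking row
barely moves — smoking only proxies COPD here, it has no direct effect on
the generated outcome.

## Known limitations

* The decile-stratified M-H estimand is a deaths-weighted average of
  per-stratum risk ratios; with coarse strata and a heavy-tailed risk
  distribution some residual within-stratum confounding is inherent,
  concentrated in the top decile (see above).
* Continuous inputs enter the refits linearly on the standardised scale; no
  splines or fractional polynomials.
* No multiple-testing adjustment is applied anywhere; intervals and
  p-values are reported unadjusted, as is conventional in this literature.
* The shipped nomogram is synthetic (see above); results under it are
  structurally meaningful but not clinically interpretable.
* Vital status is an input column; the package does no mortality-registry
  linkage and no survival-time modelling — the outcome is binary death by
  six months.
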