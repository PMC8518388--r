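---
title: "Modelling risk factors for bit-related oral lesions in trotters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling risk factors for bit-related oral lesions in trotters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitlesion)
```

## The problem

Harness-racing horses (trotters) are controlled through a bit, and
post-race oral examination frequently finds acute lesions — bruises and
wounds — at the sites where rein tension concentrates: the inner and outer
lip commissures, the bars of the mandible, the buccal area, the tongue and
the hard palate. `bitlesion` packages a complete cross-sectional
risk-factor analysis for such examinations: an ordinal lesion scoring and
severity classification, a synthetic cohort generator emulating a Finnish
trotter study population of 229 modelled horses (plus descriptively
reported ponies), and the inference pipeline an equine epidemiologist
would run on the resulting data.

## Lesion scoring and severity classes

Each acute lesion receives points by kind and size class:

| size class | bruise | wound |
|---|---|---|
| < 0.5 cm | 1 | 2 |
| 0.5–1 cm | 2 | 4 |
| > 1, < 3 cm | 3 | 6 |
| ≥ 3 cm | 4 | 8 |

A deep wound (penetrating beyond the mucosa) receives two additional
points; a "deep bruise" is rejected as a contradiction. Per-horse totals
classify severity: **A** = 0 points, **B** = 1–2, **C** = 3–11, **D** =
≥ 12 points *or* at least eight points from one single lesion. For
modelling, A–B merge to **AB** and C–D to **CD**, the binary outcome.

Three scoring conventions were genuinely open and are fixed as follows:

* **Bin boundaries.** The size bins are read literally from the inequality
  symbols of the scale: `[0, 0.5)`, `[0.5, 1]`, `(1, 3)`, `[3, ∞)` cm, so
  exactly 1.0 cm falls in the second bin and exactly 3.0 cm in the fourth.
  `size_class_from_cm()` applies this mapping to raw measurements.
* **The single-lesion override.** The severe class is defined for "eight
  points from one single lesion"; we generalise to *at least* eight points
  (a deep ≥ 3 cm wound scores ten), since severity must be monotone in
  lesion size. With the default scale the only scores above eight from one
  lesion are 10, so the generalisation affects exactly that case.
* **Old lesions** (scars, depigmentation, healed wounds) are representable
  via the `acute` flag on lesion records and always excluded from scoring.

## The synthetic cohort generator

No per-horse data were ever deposited for the study population this
package emulates, so every downstream stage is exercised on synthetic
cohorts. The generator's defaults *are* the published marginal structure:

* breed 151/229 Standardbred, 78/229 Finnhorse (pony breeds available for
  descriptive work, default weight 0);
* sex 98/102/29 gelding/mare/stallion; age truncated-normal, mean 6.9,
  SD 2.6, rounded to integer years on 3–15;
* bit-type counts 98/38/25/14/12/10/32 for snaffle trotting, Crescendo,
  mullen mouth regulator, straight plastic, Nurmos, Dr. Bristol, other;
* conditional bar-lesion probabilities by bit (0.86, 0.64, 0.50 for the
  unjointed straight plastic, mullen, Nurmos; 0.20, 0.19, 0.08 for the
  jointed Dr. Bristol, snaffle, Crescendo; 9/32 for "other");
* blood in mouth: 21% Finnhorses, 10% Standardbreds; tongue-tie 72%;
  overcheck 83%/96% by breed, with jaw strap and check bit drawn from the
  joint table (44%/44%, both 12%) conditional on an overcheck.

The binary CD outcome is drawn from a Bernoulli logistic model whose
default log odds ratios are the published adjusted estimates (Crescendo
3.6, mullen mouth regulator 9.9, straight plastic 13.7, Nurmos 1.1,
Dr. Bristol 3.9, other 1.7 versus the snaffle; mare 2.2, stallion 1.3
versus gelding; Finnhorse 1.5 versus Standardbred). The **intercept** is
not published; by default it is solved numerically (`calibrate_intercept()`,
root-finding over the exact bit × sex × breed cell mixture) so the
expected CD prevalence equals the observed 150/229. A lesion list
consistent with the drawn status is then produced by rejection sampling
(budget 10,000 draws per horse), with one lesion forced to the bars when
the horse's bar-lesion flag is drawn.

Several generator choices are synthetic conventions, not published
values, because the study reports no joint distributions: the Poisson
lesion-count means (2 for CD horses, 1 for AB), the lesion
location/kind/size/depth frequency tables, the thickness distributions
within jointedness (unjointed bits are always ≥ 18 mm, matching the
reported association of unjointed with thick/extra-thick), the
race-performance flag rates, and the breed→bit tilt (Finnhorse weights on
Crescendo and mullen multiplied by 2.2, the Standardbred row solved to
preserve the bit marginal). Consequently a cohort drawn from the defaults
matches the published *marginals* and *generating* effect sizes, but a
multivariable refit of one synthetic cohort will not numerically
reproduce the published adjusted odds-ratio table — that requires the raw
data. What the package can and does verify instead is *statistical*
correctness: 95% Wald interval coverage of every generating log odds
ratio across replicate cohorts.

The generator emulates independence everywhere the study is silent;
real examination data would carry trainer/driver clustering, correlated
equipment choices and measurement error in lesion sizing that the
synthetic cohorts do not. Passing tests therefore demonstrate that the
pipeline is correct, not that the published effect estimates are.

## The inference pipeline

`run_pipeline()` chains the stages on a scored cohort, restricted to the
two modelled breeds (ponies are summarised descriptively only):

1. **Univariable screen** — uncorrected Pearson chi-square of each factor
   against AB/CD. No Yates correction anywhere: the published
   blood-by-breed p-value (.03 from 16/78 vs 15/151) only reproduces
   without it. No multiple-testing correction is applied, as none was in
   the source analysis.
2. **Separation repair** — a factor level whose outcome is constant makes
   the logistic coefficient infinite (quasi-complete separation).
   `apply_separation_fix()` reassigns the single record at that level with
   the lowest point total (ties broken by lowest `horse_id`) to the other
   outcome and records an audit entry, mirroring how the study moved one
   three-point straight-plastic horse into the AB group.
3. **Stepwise building** — backward elimination removes, one at a time,
   the candidate with the largest factor-level joint Wald p above α = .05;
   dropped terms are offered forward re-entry; breed is forced regardless
   of significance. The factor-level p is the *joint* Wald test of all the
   factor's coefficients, not the minimum per-level p. At each removal,
   any retained coefficient changing by more than 20% (the conventional
   epidemiological confounding screen; configurable) is flagged in the
   build log. A random-intercept sensitivity check for trainer/driver is
   out of scope; the build log carries an explicit notice.
4. **Interaction scan** — each requested pair is added singly to the final
   model and tested by likelihood ratio; inestimable products (collinear
   or empty cells) are reported `NA` with the reason.
5. **Diagnostics** — sensitivity, specificity and percent correctly
   classified at a fitted-probability cut-off of 0.5 (the conventional
   choice matching "correctly classified" reporting); ROC AUC by rank
   concordance with a Hanley–McNeil interval (the study's AUC interval
   method is unstated; Hanley–McNeil is the classical default); and,
   aggregated over covariate patterns, the Pearson goodness-of-fit
   chi-square (df = patterns − parameters, `NA` when not positive),
   per-pattern Pearson residuals, leverages from the weighted hat matrix
   and standardised delta-betas `r²h/(1−h)²`.

Inference conventions: Wald (not profile) intervals with z = 1.96 — the
published intervals are symmetric on the log-odds scale, the standard
software default of the period; `fisher_exact()` uses the
"probability ≤ observed" two-sided rule (fixed-margins hypergeometric),
exact for 2 × 2 and for r × 2 totals up to 60, Monte-Carlo with 10⁵
permutations and a fixed seed beyond; `odds_ratio_2x2()` is the crude
ad/bc with a Woolf interval and a documented 0.5 continuity correction
when a cell is zero. The logistic likelihood is maximised by IRLS with
convergence tolerance 1e-8 and at most 100 iterations; non-convergence,
separation and aliased (collinear) coefficients raise distinct condition
classes.

For the bar-lesion contrast the bits collapse to unjointed (straight
plastic, mullen mouth regulator, Nurmos) versus jointed (snaffle,
Crescendo, Dr. Bristol); the heterogeneous "other" group has no
assignable jointedness and is excluded from the primary 2 × 2
(`bar_lesion_table(by = "bit_type")` gives the full r × 2 alternative —
both versions put the contrast far below p = .001).

## Numerical verification strategy

Every statistical routine is checked against an independent oracle rather
than against itself: Fisher p-values against exhaustive hypergeometric
enumeration (all 2 × 2 tables with totals ≤ 20), the chi-square statistic
against its defining formula, AUC against the O(n²) concordant-pair
count, the logistic slope against the closed-form crude odds ratio, and
severity classification against brute-force enumeration of all lesion
multisets of size ≤ 3. Null simulations confirm nominal type-I error for
the screen and the interaction test, and power simulations confirm that
the generator's bit-type signal is detected and injected interactions are
recovered. The parameter-recovery harness refits cohorts of n = 5000 over
100 replicate seeds (lesion-list simulation switched off there, since
only the binary outcome enters the refit) and requires each generating
log odds ratio to be covered by its 95% Wald interval in 90–99% of
replicates; smaller problem sizes (n = 229–2000) exercise the full
generator including lesion rejection sampling.

## Known limitations

* No mixed-effects (trainer/driver random intercept) support, no profile
  or bootstrap intervals, no multiple-testing correction — all
  deliberately outside scope.
* The generator's independence assumptions mean synthetic multivariable
  estimates match the generating coefficients, not the published adjusted
  table; the published table is a generator input, not a reproduction
  target.
* The scoring scheme covers the rostral oral cavity only, as examined in
  the source study; caudal lesions are unrepresentable.
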