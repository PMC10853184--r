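---
title: "Cortical folding variables as structural biomarkers: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical folding variables as structural biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldlaw)
```

## The model

Gyrified mammalian cortices obey, to good approximation, a universal scaling
law relating the total pial surface area $A_T$, the exposed (smoothed hull)
area $A_E$ and the average cortical thickness $T$ of a region:

$$T^{1/2} A_T = k \, A_E^{\alpha}, \qquad \alpha = 1.25 \text{ (theory)}.$$

The law derives from a biomechanical model in which white-matter axonal
tension balances the hydrostatic pressure of the cerebrospinal fluid; the
offset $k$ is interpreted as the axonal tension. Taking base-10 logarithms
and regrouping gives three linear combinations of
$(\log_{10} A_T,\ \log_{10} A_E,\ \log_{10} T^2)$ used throughout this
package:

$$K = \log_{10} k = \log_{10} A_T - \tfrac{5}{4}\log_{10} A_E + \tfrac{1}{4}\log_{10} T^2$$
$$S = \tfrac{3}{2}\log_{10} A_T - \tfrac{3}{4}\log_{10} A_E - \tfrac{9}{4}\log_{10} T^2$$
$$I = \log_{10} A_T + \log_{10} A_E + \log_{10} T^2$$

$K$ is nearly invariant across species and healthy adults, declines slowly
with healthy aging and faster in neurodegeneration — the property that makes
it a candidate "N" (neurodegeneration) biomarker. $S$ is a shape-complexity
axis, $I$ an isometric-volume axis, and $GI = A_T/A_E$ is the classical
gyrification index.

Units are fixed at mm and mm²: the variables are scale-dependent through
the log terms, so no unit auto-detection is attempted and the schema names
the units explicitly (`avg_thickness_mm`, `total_area_mm2`, ...).

### A note on the printed $S$

The coefficient vectors of $K$ and $I$ over
$(\log_{10} A_T, \log_{10} A_E, \log_{10} T^2)$ are orthogonal:
$(1, -\tfrac54, \tfrac14)\cdot(1,1,1) = 0$. The $S$ above — reproduced as
published — is orthogonal to neither, although the three axes are usually
described as perpendicular. The variant $(\tfrac32, +\tfrac34, -\tfrac94)$
*is* orthogonal to both, and `compute_folding(..., s_orthogonal = TRUE)`
provides it. The default reproduces the published definition; the
discrepancy is surfaced rather than silently fixed, and the package's tests
assert the orthogonality facts explicitly so a coefficient typo cannot pass
silently.

### Lobar measurements and the curvature correction

A lobe is an open patch of the cortical surface, so its raw areas carry a
partition-size effect. By Gauss–Bonnet, a closed hemisphere-equivalent
surface has integrated Gaussian curvature $4\pi$; a patch covering a
fraction of the surface has proportionally less. `curvature_correct()`
multiplies both areas by $4\pi / \int\!\kappa\, dA$, rescaling the patch to
a full closed surface so lobar and hemispheric $K$ are directly comparable.
The same factor is applied to $A_T$ and $A_E$ — the correction is a pure
rescaling of the partition, which affects both areas identically; the
original formulation does not restate the formula, so this same-factor
choice is a documented design decision of this package.

## Fitting and testing the law

`fit_scaling_law()` regresses $y = \log_{10}(T^{1/2} A_T)$ on
$x = \log_{10} A_E$ by ordinary least squares — the exact log form of the
law, with $R^2$ reported, matching the standard practice for this analysis.
Orthogonal (errors-in-variables) regression was considered and rejected:
the reported quantity in this literature is an OLS slope with $R^2$, and
comparability matters more than attenuation correction at the observed
noise levels. The fitted slope is compared to the theoretical
$\alpha = 1.25$ with a two-tailed Student's t-test,
$t = (\hat\alpha - 1.25)/\mathrm{SE}(\hat\alpha)$ on $n-2$ df.

The unit of analysis is one hemisphere-observation: both hemispheres of a
subject enter as separate rows. This matches the degrees of freedom
conventions of the cohort analyses this package reimplements (e.g. a
control-group age correlation on 77 subjects reporting DF = 152 = 77×2−2).
The within-subject correlation between hemispheres is therefore ignored by
the fit — a known simplification, shared with the original analysis.

## Age effects

`fit_age_model()` fits a first-order (linear) model of a variable on age.
Two open choices were decided as follows:

* **Fit group.** The model is fitted on healthy controls only and applied
  to all groups. Disease effects should not define the normal aging
  trajectory; fitting on the pooled sample would absorb part of the disease
  signal into the "aging" slope and weaken the subsequent discrimination.
* **Recentring.** Corrected values are recentred at the mean age of the
  full cohort rather than age zero, keeping them on the natural scale of
  the raw variable ($K \approx -0.5$), so cut-points before and after
  correction are comparable.

`remove_age_effect()` subtracts the fitted trend:
$K_{\mathrm{corr}} = K - \hat\beta\,( \mathrm{age} - \bar a)$. On the fit
group this residualisation is exactly decorrelating by OLS algebra; the
tests assert $|r(K_{\mathrm{corr}}, \mathrm{age})| < 0.02$ on large
simulated cohorts and idempotence under refitting.

## Group discrimination

Group means are compared by one-way ANOVA with Tukey HSD post-hoc pairwise
comparisons (family-wise adjusted p values), via `stats::aov()` and
`stats::TukeyHSD()`.

`optimal_cutpoint()` implements the cut-point criterion: the threshold
maximising sensitivity + specificity (equivalently Youden's J). Numerical
choices, all deterministic:

* **Candidates** are midpoints between adjacent distinct observed scores,
  plus $\pm\infty$. Midpoints are invariant to monotone within-gap
  placement and match common cut-point practice.
* **Tie-breaks** among equal J: highest sensitivity first (a screening
  biomarker favours sensitivity), then the lowest threshold. This makes the
  reported cut-point a pure function of the data.
* **Direction.** For $K$ and thickness, disease is the *lower* tail
  (`lower_is_positive`): group means order CTL > MCI > AD.
* **Bootstrap.** Cut-point variability is estimated by a class-stratified
  bootstrap (resampling within disease and control separately), percentile
  95% interval, 1000 resamples by default, seed mandatory. The point
  estimate is computed on the original sample; the bootstrap quantifies its
  sampling variability only.
* **AUC** uses the Mann–Whitney convention with ties counted ½, so it
  equals exhaustive concordant-pair counting exactly; the fast
  cumulative-count search is verified against a naive per-threshold oracle
  over a thousand randomised instances in the tests.

Accuracy is reported as raw correct counts over total at the chosen
cut-point (not prevalence-reweighted).

## Associations and effect sizes

`correlate()` computes pairwise-complete Pearson correlations between
clinical measures and morphology, pooled across diagnoses (the
morphology–symptom association is a property of the continuum, not of the
labels). Effect sizes use

$$d = \frac{2r}{\sqrt{1-r^2}},$$

chosen because it reproduces every printed (r, d) pair in the reference
association tables (e.g. $-0.32 \to -0.68$, $0.41 \to 0.90$,
$-0.79 \to -2.58$); the source never states the formula, so the tests pin
it with a 14-pair fixture at the tables' rounding (±0.01). One printed pair
in the thickness column (r = 0.409, d = 0.87) is *not* consistent with this
conversion (it implies 0.896); it likely reflects a differently-rounded
intermediate and is noted here rather than asserted.

Bonferroni correction is applied within the family of all (measure × ROI)
cells tested for one morphological variable; family sizes are carried in
the outputs.

`cognitive_index()` averages the z-scores of RAVLT A5, RAVLT A7, TMT A and
TMT B against user-supplied normative values by 10-year age band, with TMT
signs flipped so higher always means better. Digit Span Backward is
excluded to avoid over-representing executive function. Real normative
tables are population-specific and must be supplied by the user;
`synthetic_norms()` ships a clearly-labelled synthetic table for testing
and simulation only.

## The synthetic cohort generator

Real clinical morphometry of this kind is not redistributable, so the
package ships a generator whose defaults emulate the three-group elderly
cohort that motivates the pipeline: CTL n = 77 (age 66 ± 8.4), MCI n = 31
(72 ± 4.8), AD n = 13 (77 ± 6.1); K = −0.52 ± 0.014 / −0.53 ± 0.014 /
−0.55 ± 0.015; thickness 2.5/2.5/2.4 mm; exposed area centred on
37000 mm²; education, sex ratios, behavioral scores (cognitive index,
RAVLT A7/A5, TMT B−A, digit span) and CSF markers (Aβ1-40, Aβ1-42, t-Tau,
lipoxin, restricted to a 29/13/6 subsample) all calibrated to the same
group summaries.

Design of the generator:

* **K is the simulated primitive.** Ages are drawn per group; a latent
  subject K follows `group mean + slope × (age − reference age) + noise`;
  hemispheres add independent noise (an even variance split by default,
  configurable via `hemisphere_noise_prop`); then $A_E$ (log-Gaussian) and
  $T$ are drawn and $A_T$ is *solved from the law*. The law therefore holds
  by construction — exactly when $\alpha = 1.25$ — which is what makes the
  generator a usable oracle for the fitting code.
* **Age slope** defaults to −5·10⁻⁴ K-units/year, the value implied by a
  control-group correlation of r ≈ −0.32 with SD(K) = 0.014 and
  SD(age) = 8.4 y.
* **Exposed-area spread** is $\sigma_{\log_{10} A_E} = 0.028$, the
  delta-method image of 2400/37000 mm².
* **Lobes** are generated as surface patches: area share (frontal 0.35,
  parietal 0.25, temporal 0.25, occipital 0.15 of the hemisphere),
  integrated curvature `share × 4π`, lobe-specific K offsets (+0.06 to
  +0.19, placing lobar K in the range the lobar cut-point analyses report)
  and extra lobar K noise, constructed so that `curvature_correct()` +
  `compute_folding()` recover the intended lobar K exactly.
* **Raw score decomposition.** Only ratio/difference summaries of RAVLT and
  TMT are published, so A5 and TMT-A group parameters are the package's own
  realistic choices (A5 ≈ 10/8/7 words, TMT-A ≈ 50/70/90 s) and A7/TMT-B
  are derived to respect the published ratios/differences identically.
* **Optional AD bimodality.** A two-component mixture for the AD group
  (off by default) emulates the severely-affected subgroup visible in real
  K distributions.

What the generator does **not** emulate: non-Gaussian and bimodal real
K distributions (unless the mixture is enabled), scanner and processing
batch effects, spatially structured atrophy, education/sex effects on
morphology, and thickness–age decline. Consequently, passing tests
demonstrate that the estimators recover what the generator planted — not
that real cohorts will show the same AUCs. On simulated Gaussian groups the
CTL–AD AUC for K concentrates near the binormal closed form
$\Phi(0.03/\sqrt{0.014^2+0.015^2}) \approx 0.93$; the corresponding
empirical figure on real data (≈ 0.84) is lower precisely because real K is
not Gaussian. The package treats the binormal value as a simulator
self-consistency check, never as a reproduction of the empirical one.

## Problem sizes and Monte-Carlo tolerances

The test suite runs cohorts of the published size (121 subjects) for
end-to-end checks, 200-replicate Monte-Carlo batches for coverage
properties, a 2000–5000-subject cohort where an asymptotic property is
asserted, and ~1000 randomised small instances for the exact cut-point and
AUC oracles — sizes chosen so each property is sharply testable while the
whole suite stays fast. Coverage assertions state the nominal rate minus a
two-sigma binomial Monte-Carlo margin for the replicate count used; the
stated property is unchanged, the margin only prevents a knife-edge
assertion from flickering at finite replicate counts (e.g. a 0.16
correlation band at n = 154 is a 1.98σ band with true coverage 95.2%, which
a bare ≥95% assertion would fail almost half the time).

## Reproducibility

Every stochastic step takes an explicit seed; `run_full_analysis()` derives
per-stage sub-seeds from one root seed, restores the caller's RNG state,
and writes a JSON run report (package version, configuration hash, seed,
stage summaries) sufficient to re-execute an identical run. Fixed-seed runs
are byte-identical, and the tests assert it.

## Known limitations

* OLS ignores within-subject hemisphere correlation (SEs are mildly
  optimistic); a mixed model would be the extension.
* The linear age model is first-order by design; decade-binned or spline
  trajectories are out of scope.
* Accuracy at a cut-point on imbalanced groups is bounded below by the
  majority-class share; compare contrasts via AUC, not accuracy.
* The cognitive index requires user-supplied norms; the synthetic table is
  for tests only.

## A worked session

```{r example}
spec <- cohort_spec(seed = 2024)
cohort <- generate_cohort(spec)
analysis <- run_full_analysis(run_config(
  simulate = spec, seed = 2024, bootstrap_n = 200
))
analysis
```
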