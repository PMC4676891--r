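---
title: "Methods: ISGEO glaucoma classification and cluster-survey estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ISGEO glaucoma classification and cluster-survey estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glaucsurv)
```

This vignette documents the scientific and numerical choices behind the
package: the diagnostic procedure, the survey statistics, the synthetic
cohort generator and its calibration, and the places where a genuinely
open design question had to be settled one way or the other.

## The diagnostic procedure

Epidemiological glaucoma surveys cannot rely on longitudinal clinical
diagnosis, so the ISGEO scheme defines caseness from a cross-sectional
snapshot: structural damage (vertical cup:disc ratio, VCDR, and fellow-eye
VCDR asymmetry) referenced to percentiles of the *normal* population of
the same survey, corroborated where possible by functional damage (a
visual field defect typical of glaucoma). The package implements the
four-level variant used in the national survey it is modelled on:

| Level | Structure | Function | Other |
|---|---|---|---|
| 1 | VCDR or asymmetry ≥ 97.5th percentile | typical defect | — |
| 2 | VCDR or asymmetry ≥ 99.5th percentile | no usable result | — |
| 2b | disc seen, VCDR < 97.5th | not normal | IOP ≥ 99.5th pct and RAPD/corneal oedema |
| 3 | disc not seen | untestable | blind (VA worse than 3/60) with IOP ≥ 99.5th pct, or glaucoma history |

Two cutoff scales coexist because two measurement instruments coexist:
photographic ("image") VCDR measured on fundus photographs, and clinical
VCDR by ophthalmoscopy. Clinical grading compresses the scale relative to
photographs, so its percentile cutoffs are lower (0.60/0.70 versus
0.70/0.75). An eye's effective VCDR is the photographic value when
available, else the clinical value, and the cutoffs follow the source.
A fellow-eye asymmetry computed from mixed sources is compared against
the clinical-scale (wider) asymmetry cutoffs — the conservative choice.

Person-level aggregation takes the eye with the highest level of evidence
under the ordering 1 > 2 > 2b > 3 (descending directness of evidence; the
survey protocol states only "highest level"). Ties between eyes are
broken toward the higher VCDR, then the right eye. Glaucoma type is
`secondary` when any diagnosed eye carries a secondary cause; otherwise
gonioscopy of the defining eye separates open-angle from angle-closure
disease, and eyes without gonioscopy remain `unclassified`.

Category 3's history clause is accepted in both printed forms (surgery
for glaucoma, or diagnosed/treated glaucoma); both route through
`evidence_basis = "history"`.

## Field grading

The FDT C-20 pattern tests 17 zones of the central 20°. Each zone carries
a worst probability level (none < p<5% < p<2% < p<1% < p<0.5%), read here
as **cumulative** counts: a p<0.5% defect also counts at every shallower
level. Grading operates on the pattern-deviation probability (PDP) plot —
which also equalizes the two screening modes (C20-1/C20-5) — compared
with the total-deviation (TDP) plot, and takes the most severe satisfied
row:

* definite: ≥4 defects at p<5%, ≥3 at p<2%, ≥2 at p<1% or ≥1 at p<0.5%,
  anywhere;
* probable: within one hemifield, ≥3 at p<5%, ≥2 at p<2%, or one
  non-edge defect at p<1%;
* possible: within one hemifield, two adjacent defects at p<5% or one at
  p<2%;
* unlikely: TDP strictly better (lower total severity) than PDP, defects
  hugging the vertical meridian, or a heavily shaded TDP with a PDP
  matching no row (diffuse loss, e.g. cataract);
* otherwise normal.

Under most-severe-row precedence the grading table's "probable: 1
non-edge at p<0.5%" entry is unreachable — a single p<0.5% defect already
satisfies the definite row — and is kept in the documentation only to
mirror the printed table. Reliability: screening tests tolerate at most
one fixation error and one false positive, threshold tests at most two of
each; a failed index, a lid artefact, or untestability makes the test
unusable, and threshold results take precedence over screening results.

The instrument's printout does not define hemifields, edge zones or
adjacency, so the geometry is an explicit, configurable table
(`zone_grid()`): a 4×4 grid split by the meridians plus a central zone;
hemifield = grid half (central zone excluded from hemifield counts);
edge = zones touching the pattern boundary (the inner 2×2 ring and the
central zone are non-edge); adjacency = side-sharing within a hemifield.
The "TDP better than PDP" relation is operationalized as a strictly lower
sum of level ranks; "heavily shaded" as at least half the zones flagged;
the vertical-meridian pattern as ≥2 defects, all in one meridian-adjacent
column, present in both hemifields. Two normality rules for threshold
tests are exposed (`threshold_normal()`), because the field protocol
stated them in two non-equivalent ways; the stricter "no defects at p<1%
or p<0.5%" clause is the default.

## Normative percentiles

Cutoffs are the **nearest-rank** percentiles (the value at rank
⌈p/100·n⌉) of the 1-in-7 systematic normative subsample — no
interpolation, since VCDR is recorded on a 0.05 grid and interpolation
would fabricate unobservable values.

Removing glaucomatous eyes before taking percentiles is necessarily
single-pass (using the published cutoffs as the provisional rule) and
deliberately asymmetric. Excluding every classifiable eye would be
circular for the asymmetry criterion: the Category-2-asymmetry eyes *are*
the upper tail of the normal asymmetry distribution, and removing them
empties the very tail whose 99.5th percentile is being estimated,
collapsing the derived cutoff to the 97.5th value and inflating the
false-positive rate several-fold. The rule implemented is therefore:
Category-1 eyes (functionally corroborated) and Category-2-VCDR eyes
(absolute structural extremes, which would otherwise drag the VCDR and
IOP percentiles into the glaucomatous range) are excluded everywhere;
asymmetry percentiles are computed from structurally normal fellow-eye
pairs (both eyes below the provisional 97.5th VCDR cutoff of their scale,
neither eye Category 1). How the original survey handled this step is not
published; the vignette's rule is the package's own resolution and is
marked as such.

## Survey statistics

Prevalence is the ratio estimator with clusters as primary sampling
units; its variance is the Taylor linearization
m/(m−1)·Σᵢ(yᵢ−p̂nᵢ)²/(Σᵢnᵢ)², with a symmetric normal-approximation 95%
interval truncated to [0, 100] and the design effect defined against the
binomial variance. The exact interval construction behind the survey's
published CIs is not stated, so CI endpoints are never treated as
exactly reproducible quantities. Group differences use a Wald test of
equal level proportions with the cluster-robust covariance of the level
ratio estimators, referred to F(L−1, m−L+1) — a Rao-Scott-style
correction. Direct standardization weights band rates by a standard
population; the shipped `standard_population_synthetic()` is a synthetic
stand-in reconstructed from published per-band rates and burden (users
must supply the real census file for substantive work). Ethnic groups
with fewer than 200 participants collapse to "Others"; missing factor
values are excluded and counted.

Comparisons against cutoffs use a 10⁻⁹ epsilon so that grid values
recorded at a cutoff (VCDR 0.70, IOP 28) are never lost to floating-point
representation. Report rounding follows the survey's printed precision:
prevalences to 2 decimals, person-level proportions to 1 or 0 decimals.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 305 clusters × 45
examined persons aged ≥40; age-band weights 36.0/26.3/20.4/12.2/5.1%;
latent glaucoma prevalence 1.9/3.6/6.4/10.8/14.7% per band; a
logit-normal cluster effect (SD 1.0, intercepts solved numerically so the
marginal prevalence is preserved) giving a design effect near the
survey's planning value of 2; IOP ~ N(14, 4) mmHg in normal eyes versus
the trimodal mixture 0.50·N(12, 3²) + 0.35·N(28, 5²) + 0.15·N(50, 6²)
(mean 23.3 mmHg) in glaucomatous eyes, recorded to the nearest mmHg;
photographic grading for 66% of detailed-examination eyes with 20.5%
clinical fallback and 13.5% with no grading (partly person-level, so both
eyes are censored together more often than independence would imply, as
observed in the survey); visual fields testable for 60% of eyes; 5.6%
awareness and 7.8% secondary disease.

Measurement models and their calibration anchors:

* **Normal VCDR** = person effect 0.40 + 0.156·t plus eye effect
  N(0, 0.025), rounded to 0.05, where t is standard normal with the tail
  beyond z = 1.9 compressed by a factor 0.65 — normal discs thin out
  faster than a Gaussian. The compression pins the rounded 97.5th/99.5th
  percentiles at exactly 0.70/0.75 with margins wide enough that the
  nearest-rank derivation is stable at the subsample's size (~2 500
  eyes). Rare physiological asymmetry (1.2% of persons) offsets one eye
  by exactly 0.20 (a grid multiple, so the rounded asymmetry is exactly
  0.20), pinning the asymmetry percentiles at 0.10/0.20.
* **Clinical VCDR** = raw − 0.10 + N(0, 0.03), rounded: clinicians
  under-call cupping with extra observer noise. A slope-1 shifted model
  cannot reproduce the survey's *wider* clinical percentile gap
  (0.60→0.70), so the derived clinical 99.5th cutoffs land one 0.05 step
  below the published clinical values; only the image scale is a
  calibration anchor.
* **Affected-eye VCDR** = 0.35 + 0.65·Beta(2.6, 2.0), rounded — a
  moderately severe distribution in which roughly a quarter of truly
  glaucomatous eyes sit below the 0.70 detection cutoff.
* **Acuity** combines an age trend, person-level cataract (bilateral,
  exponential severity — the dominant non-glaucoma cause of blindness),
  and glaucomatous damage increasing in VCDR with a person-level severity
  component; cataractous eyes also feed the censoring-reason labels and
  diffuse TDP shading.
* **Angles**: 14% of primary glaucoma has closed angles; Van Herick
  grades agree with gonioscopy ~85–90% of the time; 58% of indicated
  gonioscopies are lost (field damage to lenses), driving the large
  `unclassified` type fraction.

What passing tests show — and what they do not. The classifier's
sensitivity against the latent truth is ~0.70, and percentile-defined
cutoffs with 40% missing fields guarantee a false-positive floor of
~1–1.5% of normal persons (about 0.5% of eyes lie above a 99.5th
percentile by construction; with unusable fields those are Category 2 —
the same mechanism that fills the survey's Category-2 asymmetry cell).
The two effects approximately cancel, which is precisely the regime the
original survey describes when calling its estimate "a minimal estimate";
parameter recovery therefore demonstrates calibration of this
cancellation, not unbiasedness of the case definition. A corollary: a
zero-prevalence configuration still yields ~1–2% diagnosed persons — the
false-positive floor — never exactly zero. The generator also does not
model fundus images, refraction or biometry, geographic structure beyond
cluster labels, correlation between IOP mixture components and disease
severity, or glaucoma "suspects" (outside the ISGEO scheme).

With IOP recorded to the nearest mmHg, the non-glaucomatous tail above
21 mmHg is P(N(14,4) > 21.5) = 3.0% (the continuous-scale tail beyond
1.75 SD would be 4.0%); the calibration checks use the rounding-aware
value. The derived IOP 99.5th percentile fluctuates between about 26 and
33 mmHg around the published 28, driven by residual glaucomatous eyes in
the pruned normative pool — the same mechanism that plausibly produced
the published 28 from a population whose normal-eye mean is 14 ± 4.

Randomness: one master seed; each generation stage draws from a
deterministic substream seed so that structurally identical configs
produce identical cohorts.

## Problem sizes used by the test suite

Exhaustive field-grader equivalence enumerates all 5⁸ = 390 625 level
assignments on a reduced 8-zone geometry at TDP = PDP; the classifier
truth-table grid covers ~10⁴ cells of VCDR × source × field grade × IOP ×
flags × asymmetry; CI coverage uses 1 000 simulated 100-cluster cohorts
at a common 5% prevalence; parameter recovery runs 20 full
pipeline replicates at the default 305-cluster design; percentile and
agreement properties use hundreds of randomized cases under fixed seeds.
These sizes give each stochastic check a comfortable margin relative to
its tolerance while keeping the default suite fast.

## Known limitations

* The unreachable "probable at p<0.5%" grading row and the two threshold
  normality clauses reflect genuine ambiguities in the printed protocol;
  both are surfaced in the API rather than silently resolved.
* Derived clinical-scale cutoffs sit one grid step below the published
  clinical values (see above); classification remains self-consistent on
  either threshold source.
* Visual acuity arrives as logMAR or Snellen fractions; the conversion
  uses the standard log10 lookup (6/12 = 0.30, 6/18 = 0.48, 3/60 = 1.30)
  with "worse than" meaning strictly greater logMAR, and category
  boundaries half-open on the worse side. How acuity was coded on the
  original forms is not published.
* Person-level labelling when one eye has a usable field and the other
  does not follows the per-eye rules plus highest-evidence aggregation;
  the survey's handling of this corner is unstated.
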