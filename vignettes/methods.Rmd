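---
title: "Modelling haematologic toxicity from pelvic bone-marrow dose: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling haematologic toxicity from pelvic bone-marrow dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbmtox)
```

## Scope

`pbmtox` models early haematologic toxicity in pelvic chemoradiation from
planning dosimetry. Four layers cooperate: dose–volume histogram (DVH)
handling with V5–V25 metrics, the Lyman–Kutcher–Burman (LKB) complication
model with fraction-size correction, CTCAE v4.0 grading of weekly blood
counts, and a statistical battery comparing conformal (CRT) and
intensity-modulated (IMRT) delivery groups. A synthetic cohort generator
supplies inputs with the statistical structure the analysis assumes, so the
pipeline is fully exercisable without patient data. Image-based marrow
delineation, DICOM-RT parsing and treatment planning are out of scope: the
package starts from exported DVHs.

## DVH representation and V-metrics

A differential DVH is a vector of volume fractions over half-open 0.1 Gy
bins labelled by their lower edge, so a point dose of exactly 30 Gy belongs
to the bin `[30, 30.1)` labelled 30. Bins with no volume may be omitted.
The cumulative form tabulates the fraction of volume at or above each grid
dose and is treated as piecewise linear between grid points; the two forms
are exact inverses (round-trip identity within 1e-9, property-tested).

`v_at()` implements Vx with an inclusive `>=` convention — a bin exactly at
the threshold counts in full — and linear interpolation inside a bin. At
0.1 Gy resolution interpolation versus raw bin counting changes Vx by at
most one bin's mass; interpolation was chosen because it is the standard
treatment-planning-system behaviour and makes Vx continuous in the
threshold. Arbitrary input grids are rebinned by mass-preserving
reassignment (conservation checked to 1e-6).

Relative volume fractions are the primary representation; absolute volume
in cm³ rides along as metadata, since published dose-metric tables report
both.

## The LKB model

The chain is: per-bin fraction-size correction
`LQED2 = D (1 + (D/e)/(α/β)) / (1 + 2/(α/β))`, DVH reduction
`Deff = (Σ v · LQED2^(1/n))^n`, then the probit response
`NTCP = Φ((Deff − TD50)/(m·TD50))`. Φ is the closed-form (erf-based)
normal CDF rather than numeric quadrature of the probit integral:
deterministic and accurate to better than 1e-12.

Parameter defaults and their meaning:

| parameter | default | units | role |
|---|---|---|---|
| `n` | 1 | — | volume-effect exponent; 1 treats marrow as fully parallel, making Deff the volume-weighted mean corrected dose |
| `m` | 0.09 | — | probit slope; smaller is steeper |
| `td50` | 30 | Gy | uniform effective dose at 50% complication probability |
| `alpha_beta` | 10 | Gy | linear-quadratic ratio for early-responding marrow |

These are the published maximum-likelihood estimates for grade 3+
haematologic toxicity (HT3+) of pelvic bone marrow in anal-cancer
chemoradiation with mitomycin/fluorouracil (Bazan and colleagues), together
with the published TD50 interval of 28–32 Gy. The printed `m` interval in
that literature ("0.4–0.3") cannot bracket the 0.09 point estimate in
either order; `lkb_params()` carries the sorted pair verbatim and documents
the discrepancy instead of guessing a correction, so CI-based NTCP bands
should be read with that caveat. Whether those parameters were originally
fit on EQD2-corrected or physical-dose Deff is not stated in the source;
the engine applies the correction as printed.

Multi-phase plans are combined by summing per-phase Deff values. Voxel-wise
EQD2 accumulation would be radiobiologically cleaner, but sequential-phase
DVHs are not voxel-registered, so the DVH-level sum is the only reduction
the available data support; a voxel-wise mode is deliberately absent.

NTCP confidence bands evaluate the model at the four `(m, TD50)` bound
combinations. For fixed effective dose the response is monotone in each
parameter, so the extremes over the rectangular parameter region occur at
its corners; the point estimate is forced into the envelope.

### Parameter fitting

`fit_lkb_ml()` maximizes the Bernoulli log-likelihood of `(m, TD50)` with
`n` fixed, probabilities clipped to `[1e-12, 1 − 1e-12]` to keep the
log-likelihood finite under extreme deviates. The optimizer is a
derivative-free Nelder–Mead simplex run from a 3 × 3 grid of starts across
the box m ∈ [0.01, 1], TD50 ∈ [5, 100] Gy (relative tolerance 1e-10,
best converged start wins, ties broken toward the smaller slope): the
likelihood surface is smooth but can be flat in `m` when outcomes are
nearly separable, and the multi-start simplex is robust and reproducible
without derivatives. Degenerate inputs — a single outcome class, or
non-positive doses — are refused explicitly rather than returned as
boundary estimates. 95% intervals are profile-likelihood bounds at a drop
of 1.92 log-likelihood units, root-found on the profile with the other
parameter re-maximized at every evaluation; when the profile never crosses
the threshold inside the box, the box edge is reported.

## Blood counts and grading

Weekly counts are processed as absolute values and as ratios of baseline;
nadirs are minima over observed weeks (gaps skipped, earliest week wins on
ties), and `ratio nadir × baseline = absolute nadir` holds exactly. CTCAE
v4.0 cytopenia thresholds are encoded with strict `<` at every boundary
(an ANC of exactly 1.0 is grade 2), lower limits of normal defaulting to
WCC 4.0, ANC 1.5, platelets 150 (×10⁹/L) and haemoglobin 12.0 (female) /
13.5 (male) g/dL, all overridable. Anemia grade 4 requires life-threatening
clinical criteria that count data cannot establish, so the maximum
count-derived anemia grade is 3. Baseline is never graded; HT3+ is flagged
when any lineage reaches grade 3 at any on-treatment week, and co-occurring
lineages are reported separately rather than merged.

## Statistical battery

Dose metrics are compared between delivery groups with the two-sided
Mann–Whitney U test — exact by full enumeration when the smaller group has
at most 8 tie-free observations, otherwise the tie- and
continuity-corrected normal approximation. Blood endpoints use Welch's
unequal-variance t-test, with the all-degenerate case resolved by
convention (equal means p = 1; unequal means p = 0, flagged). Linear and
logistic regressions are ordinary `lm`/`glm` fits behind a stable result
schema (beta, SE, two-sided p, n); exact fits report the floor p = 1e-12
rather than zero, and logistic separation is refused loudly. Covariates are
coded female = 1, T3/4 = 1, node-positive = 1.

Multiple testing uses Holm's step-down by default, applied independently
within families keyed by (group, structure, analyte, endpoint) so that the
five V-levels of one structure against one blood count form one family;
Benjamini–Hochberg is available as a flag. The source literature names both
Holm–Bonferroni and a 5% false-discovery-rate control, which are different
error criteria; Holm is the default here because it is the named method,
and BH is retained as the configured alternative. For the multivariable
models, the implemented choice is "clinical covariates plus one dose metric
per model": dose metrics at adjacent V-levels are nearly collinear, so
fitting them jointly would be rank-degenerate by design.

## The synthetic cohort generator

The generator's defaults encode the study conditions the package is
calibrated to: 25 CRT and 21 IMRT patients; per-structure, per-group
dose-metric means and SDs from `dose_metric_calibration()`; covariate rates
(female 27/46, T3–4 23/46, node-positive 19/46; age mean 66 on 44–88, SD
taken as range/4 = 11); and prescriptions of 30.6 Gy/17 fractions plus
19.8 Gy/11 fractions (CRT, two phases) versus 28 fractions (IMRT).

**Dose metrics.** Published tables give marginal means and SDs per V-level
but not their joint distribution. Independent draws would violate the
structural ordering V5 ≥ … ≥ V25 constantly and understate regression
power, so levels share a patient-level random effect (correlation 0.7
across levels) with truncated-normal marginals on [0, 100], followed by an
isotonic (pool-adjacent-violators) projection onto decreasing sequences.
Degenerate SDs (lower-pelvis IMRT V5 at 100.0 ± 0.0) are point masses. The
projection leaves mid-level means essentially unbiased (violations pull a
level up from above and down from below symmetrically), which is why the
calibration checks target V10.

**DVH shape.** The cumulative curve passes exactly through (0 Gy, 100%),
the five drawn knots at 5–25 Gy, then decays linearly to zero at the plan
maximum (50.4 Gy summed CRT; 53.2 × 1.05 = 55.9 Gy IMRT), and is converted
to differential form on the 0.1 Gy grid. The tail above 25 Gy is entirely
unconstrained by the published tables, and Deff integrates the whole curve
— this is precisely why cohort-level mean NTCP values from the source study
are not reproduction targets for the generator. For the two-phase CRT
plans, per-phase DVHs are obtained by scaling the summed-plan bin doses in
proportion to each phase's prescription: the same spatial dose pattern
delivered in two intensity-scaled instalments, the weakest but simplest
assumption available without voxel data.

**Bloods.** Baselines are truncated normals at the published cohort means
with SD backfilled as range/4 (the tables print ranges, not SDs — an
explicit assumption), shifted down for female patients (WCC −0.89 and ANC
−0.70, matching the published univariate covariate betas; haemoglobin −1.0
g/dL and platelets −20 as physiologic choices). Weekly ratios follow
`clip(1 − S·g_w·ε, 0.05, 1.10)` with the week-1..5 template
`g = (0.35, 0.70, 1.00, 0.95, 0.60)` — nadir at weeks 2–3, recovery from
week 4 — lognormal weekly noise (σ = 0.10), a per-patient lognormal frailty
(σ = 0.15), and susceptibilities coupling each analyte to dose:
`S_wcc = 0.010 × iliac V10`, `S_anc = 0.015 × mean(iliac, lumbosacral) V10`
(the published ~1%/1–2% relative suppression per percent V10),
`S_hgb = 0.002 × iliac V10` and `S_plats = 0.0055 × lower-pelvis V10`,
both chosen to land the simulated nadir ratios in the published ranges
(haemoglobin barely suppressed; platelet nadir ratios near 0.5).

Two consequences of these fixed defaults are worth knowing. First, because
week 4's template weight (0.95) sits within one noise SD of week 3's peak,
roughly a third of simulated nadirs fall at week 4; the mode stays at
weeks 2–3. Second, the ANC slope applied proportionally to IMRT-scale V10
values (~70%) drives many simulated IMRT ANC ratios onto the 0.05 floor, so
blood-derived HT3+ rates in synthetic IMRT patients are far higher than any
clinical cohort's — the generator reproduces suppression *slopes* for
recovery testing, not clinical toxicity rates. Ground-truth HT3+ labels are
therefore drawn separately as Bernoulli(NTCP(Deff)) from the whole-pelvis
effective dose, which is what the parameter-recovery tests consume.

All randomness flows from one seed through a single stream in fixed
per-patient order (covariates, DVHs, bloods, outcome), so a fixed seed
yields byte-identical cohort files.

**What passing tests do and do not show.** The generator produces the
configured marginal distributions, orderings and couplings; it does not
produce anatomically realistic DVH shapes beyond the knot model, correlated
missingness, transfusion support, chemotherapy dose modifications, or any
relation between covariates and dose metrics. Pipeline results on synthetic
cohorts validate the *machinery* — metric extraction, model evaluation,
test calibration, recovery of generating parameters — not clinical effect
sizes.

## Numerical choices

- Bisection and profile roots use absolute tolerances of 1e-9 and 1e-7 on
  well-conditioned monotone functions.
- Exact Mann–Whitney p-values follow the `2 × min(tail)` two-sided
  convention, matching the enumeration oracle used in tests.
- NTCP clipping at 1e-12 inside the likelihood bounds the per-observation
  log-likelihood at ~−27.6, keeping the surface finite without affecting
  estimates away from separation.
- Problem sizes: parameter recovery uses 20 replicates of 2000 patients;
  generator calibration 1000 DVHs per group; null-calibration of the
  regression battery 1000 replicate 46-patient cohorts via the generator's
  metric and blood paths. These sizes put Monte-Carlo error comfortably
  inside the tolerances asserted.

## Known limitations

- The m confidence interval propagated into NTCP bands inherits the
  inconsistency in its published source (see above).
- Active (FLT-PET-defined) marrow distribution is ignored; all marrow
  volume is weighted equally, as in the DVH-based literature the defaults
  come from.
- Phase splitting by dose scaling is an approximation; plans whose phases
  irradiate genuinely different sub-volumes need per-phase DVH input, which
  the reader supports directly.
- The grading layer caps anemia at grade 3 from counts alone and carries no
  transfusion information.
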