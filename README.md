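# pbmtox

Pelvic radiotherapy irradiates a large share of the body's proliferating
bone marrow, and in anal-cancer chemoradiation the resulting cytopenias —
leukopenia, neutropenia, thrombocytopenia — are a dose-limiting toxicity.
`pbmtox` is an R package for clinical physicists and outcome modellers who
want to quantify that risk from planning data: it turns per-structure
dose–volume histograms (DVHs) of pelvic bone marrow and its iliac,
lumbosacral and lower-pelvis subdivisions into V5–V25 dose metrics,
propagates them through the Lyman–Kutcher–Burman (LKB) complication model,
grades weekly blood counts against CTCAE v4.0, and runs the standard
group-comparison and regression battery used to contrast conformal (CRT)
and intensity-modulated (IMRT) delivery.

## The model

The LKB model reduces a DVH to an effective uniform dose and maps it to a
complication probability through a probit response:

    NTCP = Φ(x),            x = (Deff − TD50) / (m · TD50)
    Deff = ( Σᵢ vᵢ · LQED2ᵢ^(1/n) )ⁿ
    LQED2ᵢ = Dᵢ · (1 + (Dᵢ/e)/(α/β)) / (1 + 2/(α/β))

where `vᵢ` is the volume fraction in the 0.1 Gy dose bin `Dᵢ`, `e` the
number of fractions, and `LQED2` the linear-quadratic conversion of each
bin dose to its 2 Gy-per-fraction equivalent. Defaults are the published
pelvic-bone-marrow fit for grade 3+ haematologic toxicity (HT3+): `n = 1`
(fully parallel organ), `m = 0.09`, `TD50 = 30 Gy`, `α/β = 10 Gy`.
Sequential plan phases (the two-phase conformal technique) are combined by
summing per-phase effective doses. `fit_lkb_ml()` re-estimates `(m, TD50)`
from binary outcomes by maximum likelihood with profile-likelihood
confidence intervals.

Because no patient-level data ship with the package, a calibrated synthetic
cohort generator (`generate_cohort()`) emulates the two delivery groups —
25 CRT / 21 IMRT patients, dose-metric distributions per structure and
group, weekly blood-count suppression peaking at weeks 2–3, and HT3+ ground
truth drawn from the LKB model — so the entire pipeline is testable end to
end.

## Worked example

```r
library(pbmtox)

# a toy whole-pelvis DVH: half the marrow at 10 Gy, half at 30 Gy
d <- dvh(dose_gy = c(10, 30), volume_fraction = c(0.5, 0.5),
         total_volume_ccm = 1400, structure = "whole_pelvis")
dose_metrics(d)
#>      structure volume_ccm  v5 v10 v15 v20 v25
#> 1 whole_pelvis       1400 100 100  50  50  50

ph <- plan_phase(list(whole_pelvis = d), n_fractions = 28)
ntcp(deff_plan(list(ph), "whole_pelvis", lkb_params()), lkb_params())
#> Deff = 18.155 Gy  x = -4.3871  NTCP = 0.0000  [CI 0.0000-0.1897]
```

The effective dose of 18.2 Gy sits far below TD50 = 30 Gy, so the predicted
complication probability is negligible; the upper CI bound (0.19) reflects
the published parameter uncertainty. On a full synthetic cohort:

```r
co <- generate_cohort(generator_config(), seed = 42)
b  <- run_comparison(co)
b$ntcp_summary
#>   group mean_deff mean_ntcp mean_ntcp_low mean_ntcp_high ht3_observed_rate
#> 1   CRT      19.7   0.00612       0.00612          0.242             0.120
#> 2  IMRT      28.9   0.36877       0.30010          0.557             0.857
```

IMRT's broader low-dose bath pushes its mean effective whole-pelvis dose
(28.9 Gy) close to TD50, so the model predicts a much higher complication
probability than for the two-phase conformal plans (19.7 Gy). The
`dose_comparison` table shows every whole-pelvis V-level significantly
higher under IMRT (Mann–Whitney p < 1e-5), and `regression` holds the
Holm-corrected dose-metric/blood-count associations. A command-line wrapper
with `simulate`, `metrics`, `ntcp` and `run` verbs lives at
`inst/cli/pbmtox.R`.

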