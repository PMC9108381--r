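# ichcea

Cost-utility analysis of minimally invasive surgery (MIS) for spontaneous
intracerebral hemorrhage (ICH), built as a real-life implementation model
for a single stroke centre.

Spontaneous ICH kills or disables most of the patients it strikes, and the
two emerging MIS techniques — catheter evacuation plus thrombolysis and
endoscopic aspiration — promise better functional outcomes at a visibly
higher procedural cost. A centre weighing adoption needs to know (i) what
fraction of its admitted ICH patients would qualify under the surgical
trials' criteria and (ii) the incremental cost per quality-adjusted life
year (QALY) of operating on them. `ichcea` answers both with a tidyverse
pipeline aimed at health-economics and clinical-research users:

* **Cohorts** — a validated patient-level table (one row per admission:
  GCS, NIHSS, ABC/2 hematoma volume, stays, modified Rankin Scale (mRS)
  outcomes) with strict CSV round-tripping, plus a seeded synthetic
  generator calibrated to a published admission-year registry (n = 137)
  with a Gaussian-copula latent severity coupling volume, severity scores,
  stays and outcomes.
* **Eligibility** — a declarative rule engine with shipped rule sets for
  MISTIE III, DIST, ENRICH and INVEST (volume floors, time windows,
  premorbid mRS caps, hematoma-stability on repeat imaging), per-criterion
  failure reporting and an explicit policy for missing data.
* **Costing** — every strategy priced from the same tariff line items:
  operating-room minutes, surgical pack, navigation, procedure-specific
  material, per-diem ICU/Stroke-Unit/ward stays, and 90-day
  rehabilitation costs; conservative arms weight the rescue-craniotomy
  cost by its cohort probability.
* **Effectiveness** — mRS-to-utility maps (death pinned at 0) turned into
  arm QALYs over a one-year horizon, good-outcome (mRS <= 3) and 30-day
  survival fractions.
* **Economics** — the incremental cost-effectiveness ratio
  `ICER = (C_MIS - C_conv) / (E_MIS - E_conv)` with dominance handling,
  cost-utility quadrants, net health/monetary benefit at a
  willingness-to-pay threshold `lambda` (NHB = dE - dC/lambda,
  NMB = lambda dE - dC; default lambda = 30,000 EUR/QALY), and the effect
  size required to meet the threshold.
* **Uncertainty** — probabilistic sensitivity analysis: nonparametric
  bootstrap of the cohort arm jointly over costs and utilities,
  Dirichlet/gamma/truncated-normal resampling of the literature arm,
  cost-utility planes and cost-effectiveness acceptability curves
  (`ggplot2::autoplot()` methods included).

## Worked example

The packaged fixtures reproduce the published comparison of each MIS
technique against the centre's own conventionally managed candidate
subgroup:

```r
library(ichcea)

reproduce_reference_costs()[, c("arm", "hospital_total", "total_with_social")]
#>   arm                             hospital_total total_with_social
#> 1 mistie3_candidates_conventional         14190.            20404.
#> 2 mistie3_intervention                    33126               NA
#> 3 dist_candidates_conventional            13487.            18407.
#> 4 kellner_intervention                    23319.            31505.

reference_scenario("catheter")
#> <econ_comparison> catheter
#>   cost:  MIS 33126.00 vs conventional 14189.81  (delta 18936.19 EUR)
#>   QALY:  MIS 0.320 vs conventional 0.090  (delta 0.230)
#>   ICER: 82331.25 EUR/QALY  [quadrant NE]
#>   at lambda = 30000: NHB -0.4012 QALY, NMB -12036.19 EUR; required MIS QALY 0.72
```

Read: conventional management of catheter-candidates costs ~14,190 EUR
per patient against ~33,126 EUR for the catheter intervention; at 0.23
incremental QALY the ICER is ~82,300 EUR/QALY — north-east quadrant
(costlier, more effective), not cost-effective at the local 30,000
EUR/QALY threshold, and the intervention would need to reach 0.72 QALY to
meet it. The endoscopic comparison (`reference_scenario("endoscopic")`) gives
~75,050 EUR/QALY and a required 0.56 QALY, so the endoscopic technique is
the more favourable of the two.

A fully synthetic end-to-end run — generate a registry, screen it, cost
both strategies, compare, and quantify uncertainty:

```r
res <- run_report(out_dir = "run1", trial = "dist",
                  params = cohort_gen_params(n = 137, seed = 1),
                  n_replicates = 500)
res$manifest$n_candidates      # 66 of 137 pass the endoscopy-trial screen
res$comparison                 # synthetic-cohort ICER, NE quadrant
wtp_at_probability(res$ceac, 0.5)  # NA: 50% not reached on the default grid
autoplot(res$replicates)       # cost-utility plane
autoplot(res$ceac)             # acceptability curve
```

`run_report()` writes `cohort.csv`, `screening.csv`, `costs.csv`,
`comparison.json`, `replicates.csv`, `ceac.csv` and a `manifest.json`
(seed, configuration, versions) from which every artifact regenerates;
identical configuration and seed give byte-identical outputs.

See `vignette("implementation-model")` for the model's assumptions,
distribution choices and limitations.

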