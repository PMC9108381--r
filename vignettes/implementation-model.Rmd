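---
title: "A real-life implementation model for minimally invasive ICH surgery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A real-life implementation model for minimally invasive ICH surgery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichcea)
library(dplyr)
```

## The question the model answers

Minimally invasive surgical (MIS) evacuation of spontaneous intracerebral
hemorrhage (ICH) — catheter aspiration plus thrombolysis, or endoscopic
aspiration — is more expensive than conservative management but may improve
functional outcomes. Before a stroke centre adopts an MIS protocol it needs
two numbers: how many of its admitted ICH patients would actually qualify
for surgery under the trial criteria, and what the incremental cost per
quality-adjusted life year (QALY) of operating on them would be. `ichcea`
models both from the perspective of a single tertiary centre: a cohort of
admitted patients is screened against trial eligibility rules, each
treatment strategy is priced from tariff line items, modified Rankin Scale
(mRS) outcomes are converted to QALYs over a one-year horizon, and the two
strategies are compared on the cost-utility plane.

## Cohort model and synthetic generation

A cohort is a tibble with one row per patient
(`cohort_columns()` lists the schema): demographics, admission severity
(GCS, NIHSS), imaging (initial and control hematoma volume, measured in
practice with the bedside ABC/2 ellipsoid approximation implemented in
`abc2_volume()`), resource use (ICU / Stroke-Unit / total stays, rescue
craniotomy, EVD) and outcomes (discharge destination, mRS at discharge and
midterm, 30-day survival). `validate_cohort()` enforces the cross-field
invariants — stays nest inside the total stay, death as discharge
destination coincides with mRS 6, death within 30 days implies in-hospital
death — and the CSV reader/writer round-trips exactly, with empty cells as
the only missing-value encoding.

Because patient-level registry data of this kind are never public, the
package ships a seeded generator, `generate_cohort()`, whose defaults are
calibrated to the admission-year registry of the reference centre
(n = 137): age 69 (SD 15.1) years, 59.1% male, mean hematoma volume 35 ml
(SD 42), NIHSS median 12, hematoma expansion (>5 ml growth) in a third of
controlled scans, rescue craniotomy in 13.1%, and length-of-stay moments of
2 ± 7.8 d (ICU), 2 ± 2.6 d (Stroke Unit) and 15 ± 20.8 d (total). The
registry reports only moments and medians, so the distribution
families are this package's own choices:

* **Age** — normal truncated to [18, 100]; the location is solved with
  `uniroot()` so the *truncated* mean equals the target (naive truncation
  would bias the mean down by ~0.7 y).
* **Volume** — log-normal re-parameterised to the mean/SD (a normal with
  SD larger than its mean would go negative).
* **Stays** — gamma matched by moments; the ward component is generated
  as an explicit remainder so `los_icu + los_stroke_unit <= los_total`
  holds by construction, not by rejection.
* **NIHSS** — a scaled beta with its median matched to 12/42.
* **Triage-to-image and onset-to-admission times** — log-normal around the
  reported medians, the latter truncated at the 48 h selection window.

Severity coupling is the one structural assumption: the registry implies
but never quantifies that large hematomas, poor GCS, long stays and poor
mRS travel together. Each patient draws a single standard-normal latent
severity; every severity-related marginal is sampled through its quantile
function from a uniform correlated with that latent draw (a Gaussian
copula), with strength `severity_coupling` (default 0.6, a moderate
dependence chosen once; 0 gives independence, 1 comonotonicity — both ends
are exercised by the tests). Because the copula preserves marginals
exactly, calibration tests at n = 5000 check each marginal against its
target inside a 99% Monte-Carlo interval. Each field draws from its own
seed substream, so adding a field never perturbs the draws of existing
ones and cohorts are bit-reproducible.

What the generator does *not* emulate: secular trends, site effects,
informative missingness (missing control scans and midterm assessments are
missing completely at random here), and any treatment effect of surgery on
outcome within the cohort. A green calibration suite therefore says the
pipeline's arithmetic is right under plausible inputs, not that the
eligibility proportions of any particular hospital are predicted.

## Eligibility screening

`builtin_ruleset()` encodes the selection criteria of the four surgical
trials (MISTIE III, DIST, ENRICH, INVEST) plus the registry's own
`study_selection` filter (supratentorial location, admission within 48 h,
premorbid mRS <= 3). The criteria are declarative `{field, op, value,
label}` records evaluated by a small engine; unknown fields fail at
configuration time, and composite clinical constructs (hematoma stability
on a repeat scan at least 6 h later with growth under 5 ml; the
"GCS <= 14 or NIHSS >= 6" severity gate) are derived quantities with their
own names. The exact criteria lists applied at the reference centre's screening were
never published in full, so these defaults are reconstructed from the
trials' protocols; every rule set is overridable from a
YAML file and the screening report records the active rules, keeping any
divergence auditable. A criterion touching a missing field is
*indeterminate*: under the default conservative policy the patient is
ineligible with the reason recorded, under the optimistic policy the
criterion passes — the spread between the two policies is the sensitivity
of the screening count to missingness. Whether the 72 h catheter-trial
window should be tested against onset-to-admission or a hypothetical
onset-to-surgery time is not publicly specified; the default uses
onset-to-admission, the looser and observable reading.

## Costing

Every strategy is priced from the same tariff line items
(`tariff_table()`, defaults from the centre's 2020/2021 public tariff):
5 EUR per operating-room minute, 1,150 EUR surgical pack, 862 EUR
neuronavigation, procedure-specific material (200 EUR catheter set,
7,000 EUR endoscopic consumables), and per-diems of 1,175.9 / 707.4 /
419 / 97.8 EUR for ICU, Stroke Unit, ward and rehabilitation facility.
The published tables print an "operating room" line *and* its
constituents; the only reading under which the printed totals reconcile is
that the line is a subtotal of the rows beneath it, and `surgery_subtotal()`
implements exactly that — nothing is double-counted. In the conservative
arm no surgery is planned but a fraction of patients deteriorates into
rescue craniotomy; `conservative_arm_cost()` weights the rescue subtotal
by the exact cohort fraction (5/17 and 10/59 — the printed 529.2 EUR cell
is 1,800 x 0.294), while `mis_arm_cost()` charges the intervention to
every patient. Social costs charge the rehabilitation per-diem over a
90-day horizon to the fraction discharged to a secondary facility. All
arithmetic is full floating precision; recomputed cells differ from the
printed ones by at most ~0.01%, which is table rounding of the published
operands. The per-patient router `cost_per_patient()` applies the same
line-item logic to individual records, and its cohort mean equals the
aggregate arm cost to 1e-6 EUR — a deliberate brute-force-versus-aggregate
oracle pair. The endoscopic literature arm's cost lines use 8.5 ICU and
8.5 ward days while the same publication reports stay *medians* of 9 and
17 days; the fixture carries both, defaulting to the cost-line values
because the published cost arithmetic uses them.

## Outcomes and QALYs

Midterm mRS distributions are converted to QALYs by a utility map over mRS
0–6 with death pinned at exactly zero, multiplied by a one-year horizon
with no discounting. The published group QALYs (0.09 / 0.32 and
0.234 / 0.365) rest on a regression-based utility model whose coefficients
are not printed, so they are **not derivable** from any shipped preset;
the economic layer therefore accepts arm QALYs directly as operands
(`reference_scenario()` pins the published ones), and the shipped `"linear"`
preset `u = (6 - mRS)/6` serves synthetic analyses. The QALY operator is
linear in the map and the horizon, and with an all-ones utility map it
collapses to the midterm survival fraction — both closed-form properties
are tested in place of the unpublishable coefficients. The default
denominator is patients with a counted midterm mRS (deaths included);
an enrolled-denominator variant is available for sensitivity checks.

## Economic comparison

`compare_strategies()` assembles incremental cost, incremental effect, the
ICER, the cost-utility quadrant, net health benefit
(NHB = dE - dC/lambda) and net monetary benefit (NMB = lambda dE - dC) at
the willingness-to-pay threshold (default 30,000 EUR/QALY, the accepted
local threshold), and the effect size the intervention would need for its
ICER to hit the threshold exactly (`required_qaly_at_threshold()`, the
inverse of the ICER in its effect argument — the round trip is tested to
1e-9). A negative or zero incremental effect never yields a signed ICER:
those cases carry dominance tags (`"dominant"`, `"dominated"`,
`"indeterminate"`, `"less_costly_less_effective"`) because the raw ratio
inverts its meaning across the axis; the unsafe ratio remains available
for plotting. Equal costs give an ICER of 0 regardless of the effect sign.

## Probabilistic sensitivity analysis

The reference comparison's replicate cloud and acceptability curves come
with no published resampling scheme, so the scheme here is the package's
own and its published 50% crossings (62,000 / 69,000 EUR/QALY) are treated
as order-of-magnitude calibration checks, never as exact targets. Each
replicate:

* **bootstraps the conservative cohort** nonparametrically — patients are
  resampled with replacement, and each patient carries their line-item
  cost and their midterm-mRS utility jointly, preserving the within-
  patient cost-outcome dependence;
* **resamples the literature arm parametrically** — midterm mRS weights
  from a Dirichlet(counts + 1) posterior (the +1 smooths zero cells),
  stays from moment-matched gammas with spreads derived from the reported
  ranges (range/4), and operating-room minutes from a normal truncated at
  zero.

Cost-effectiveness at a threshold is *strict* positivity of the net
monetary benefit, so a replicate exactly on the line is not
cost-effective and the single-replicate acceptability curve is an
unambiguous step function. The CEAC probability at every grid point equals
a brute-force count over replicates (tested), its small-lambda limit is
the fraction of cost-saving replicates and its large-lambda limit the
fraction of QALY-gaining ones. `wtp_at_probability()` interpolates
linearly between grid points and returns an explicit not-reached marker
when the curve never attains the target. Defaults: 5,000 replicates,
lambda grid 0–150,000 by 1,000; the test suite uses a few hundred
replicates, which keeps the full suite under ten seconds while leaving
bootstrap-consistency checks two Monte-Carlo standard errors wide.

Because the per-patient source records behind the published candidate
subgroups are unavailable, `reference_cohort()` reconstructs *synthetic*
patient-level tables whose aggregates equal the printed subgroup summaries
exactly (stays at the cost-line values, rescue indicators at 5/17 and
10/59, midterm mRS counts as published). That is what the packaged PSA
scenario bootstraps; on it, over 90% of replicates land in the north-east
quadrant (costlier, more effective), matching the published qualitative
finding, and the 50% acceptability crossing sits in the published order of
magnitude. One reconciliation note: the endoscopic subgroup reports 14
deaths at 30 days against 13 in-hospital deaths; the patient-level
reconstruction uses 13 because a 30-day death must be an in-hospital death
under the schema invariant, while the frozen arm fixture reports the
published 14/59.

## Worked example

```{r example}
# deterministic published comparison, catheter technique
cath <- reference_scenario("catheter")
cath
glance(cath)

# full synthetic pipeline at a small replicate count
res <- run_report(out_dir = NULL, trial = "dist",
                  params = cohort_gen_params(n = 137, seed = 1),
                  n_replicates = 500)
res$comparison
res$manifest$n_candidates
wtp_at_probability(res$ceac, 0.5)
```

## Known limitations

* The cohort generator's independence assumptions (missingness, sex,
  antithrombotics vs severity) are simplifications; only the severity
  block is coupled.
* The eligibility defaults are protocol reconstructions, not the
  unpublished screening lists of the reference centre; screening proportions on
  synthetic cohorts are calibration bands, not predictions.
* The one-year horizon without discounting follows the reference
  analysis' design; no
  multi-year Markov extrapolation is attempted.
* Published group QALYs enter as operands, not outputs, because their
  utility model is unpublished; all QALY machinery is validated through
  closed-form properties instead.
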