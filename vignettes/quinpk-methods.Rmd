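---
title: "quinpk: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quinpk: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quinpk)
```

quinpk addresses two linked questions about chloroquine (CQ) and
hydroxychloroquine (HCQ) dosing for COVID-19 treatment and prophylaxis:
what whole-blood concentrations do the candidate regimens produce across
the adult weight range, and how do those concentrations compare with the
exposure region where self-poisoning data show mortality? This vignette
explains the models, their assumptions, the parameters that matter, and
the design choices made where more than one defensible option existed.

## Dose and regimen arithmetic

Tablets are formulated as salts but regimens are defined in base
equivalents; the base fraction is the molecular-weight ratio. Chloroquine
diphosphate 250 mg and hydroxychloroquine sulphate 200 mg both contain
155 mg base, and the package expresses every schedule in 155-mg tablet
units (the nominal rounded tablet base mass, not the exact quotient,
because the regimens themselves are stated in those units).

```{r}
cq <- drug_formulation("chloroquine")
salt_to_base(250, cq, round = TRUE)
```

Treatment schedules follow the trial regimens: a loading dose at 0 and
6 h, maintenance every 12 h starting 12 h after the first dose, for 7 or
10 days. The schedule-end convention is that maintenance doses fall
strictly before `days * 24` hours, giving 13 (7-day) or 19 (10-day)
maintenance doses; the alternative (ending on the dose at `days * 24`)
is equally consistent with "a total treatment duration of 7 or 10 days",
and we fixed the open choice on the strictly-before side so that the
7-day flat schedule totals 5,270 mg base. Weight-based variants quantise
each loading administration to 3–5 whole tablets targeting 10 mg base/kg
and (optionally) maintenance to 1–3 tablets targeting 5 mg base/kg per
12 h. Quantisation minimises the absolute deviation from the target;
ties break toward fewer tablets, the safety-conservative direction.
Prophylaxis is one weight-based loading dose then one tablet daily
(2.5 mg base/kg/day at 62 kg) for `months` 30-day months. Weights outside
the simulated 40–90 kg adult range warn rather than fail, since the
arithmetic itself stays valid.

## The population PK model

Disposition is a linear mammillary model — one central compartment with
first-order elimination plus one (default) or two peripheral
compartments — with first-order oral absorption and an absorption lag.
The default of a single peripheral compartment reflects the single
inter-compartmental clearance in the parameterisation; a second
peripheral compartment is available (`q_f`/`vp_f` of length 2) because
descriptions of these drugs' kinetics sometimes use deep and shallow
peripheral spaces. The model structure is recorded with simulation
output so runs are self-describing.

The profile is computed analytically: the depot + disposition system is
linear with constant coefficients, so the central-compartment amount
after a unit dose is a sum of exponential modes obtained from the
eigendecomposition of the rate matrix, and multi-dose profiles are
superpositions of shifted single-dose solutions. This is exact (to
machine precision) rather than an ODE approximation; the test suite
verifies it against an independent stiff ODE solution to better than
1e-6 relative error. The one numerical guard: if `ka` coincides with a
disposition eigenvalue (a measure-zero configuration where the
eigenbasis degenerates) it is perturbed by one part in 1e7.

Amounts in mg base convert to micromolar whole blood as
`mg / Vc * 1000 / MW`. Parameters are treated as whole-blood referenced
throughout; the blood:plasma ratio is used only to scale
plasma-referenced in vitro EC50 values (1.13 uM x 3 = 3.39 uM for CQ,
0.72 uM x 4 = 2.88 uM for HCQ), never to convert profiles.

Between-patient variability is exponential: each structural parameter is
multiplied by `exp(eta)`, `eta ~ N(0, omega^2)` independently, with
`omega = 0.30`. We read the stated "30% added exponentially" as the
log-scale SD (the common pharmacometric shorthand); the geometric CV
this implies, 30.7%, is within a percentage point of reading it as a CV,
and the distinction is below every tolerance used here. Allometric
scaling uses the standard exponents — 0.75 on clearances, 1.0 on
volumes — about a 62-kg reference, the standard patient at which
4 tablets equal exactly 10 mg base/kg.

Renal impairment multiplies total clearance by
`1 - renal_fraction * impairment_fraction` with no compensatory hepatic
increase; the worst case (renal fraction 0.5, 90% loss) is a 45%
reduction, which raises steady-state average concentrations by 1/0.55.

### Illustrative parameter values

The published population estimates behind the original simulations are
not reproduced here; `make_fixture_pk_set()` ships parameter sets that
are explicitly ILLUSTRATIVE. They are constructed to satisfy the drugs'
well-established qualitative pharmacology — terminal elimination
half-life over 28 days (the fixtures give roughly 52 days for CQ and
43 days for HCQ), total apparent distribution volume above 100 L/kg at
62 kg, absorption on the hours scale — so simulated bands have realistic
shape, but no quantitative claim about published concentration bands
should be based on them. Every acceptance-level check of the PK engine
is therefore a property (oracle agreement, linearity, superposition,
sampling-distribution recovery, interval coverage, the AUC identity),
not a comparison of concentrations to published figures.

### Exposure summaries

`summarize_population()` reports the pointwise arithmetic mean and the
95% prediction interval as empirical 2.5th/97.5th percentiles across
simulated subjects (type-7 quantiles, i.e. linear interpolation between
order statistics) — a percentile band, not mean ± 2 SD; at n = 1,000 the
difference between percentile definitions is far below any tolerance
used. Per-subject Cmax and AUC use the trapezoidal rule on the
simulation grid with a horizon of one month — 720 h exactly — after the
last dose. The default grid is 1-h steps over the dosing period then
24-h steps to the horizon.

## The self-poisoning mortality analysis

Admission whole-blood concentrations in the pooled overdose cohorts were
measured by UV-spectrophotometry, which co-measures desethylchloroquine;
records are therefore CQ + metabolite in uM, and
`parent_fraction_correction()` maps a total concentration to parent
equivalent assuming ~30% metabolite (15 uM total is about 10.5 uM
parent, the basis of the ~10 uM whole-blood safety bound).

`binned_mortality()` groups patients into half-open `[lower, upper)`
concentration bins and attaches 95% percentile-bootstrap confidence
intervals, resampling patients with replacement within each bin
(B = 2,000 by default, seeded). The bin edges are not dictated by the
analysis being emulated, so the defaults
(0, 5, 10, 15, 20, 25, 30, 40, 55, 85 uM) align bin boundaries with the
15/20/25 uM thresholds the threshold statistics quote. Empty bins are
reported with `NA` mortality rather than dropped, so bin counts always
sum to the cohort size. Reported group percentages follow the usual
quoting convention: integers, except one decimal below 1% (1/106 reads
0.9%, 13/61 reads 21%). With a zero cell the odds ratio is reported both
unadjusted and Haldane-Anscombe corrected.

## The synthetic-data generator

`generate_poisoning_cohort()` draws admission concentrations from a
log-normal truncated to 1–85 uM (log-median `log(9)`, log-SD 0.6 —
median ~9 uM with a heavy right tail, matching the qualitative
concentration spread of pooled overdose admissions) and outcomes from a
logistic law `P(death) = plogis((conc - c50) / steepness)` with
`c50 = 30` uM. The steepness default, 2 uM, was fixed by a one-off
calibration simulation: across 200 seeded replicates of n = 258, the
zero-death threshold on the 5–25 uM grid is at least 15 uM in ~99% of
replicates and mortality above 20 uM exceeds 5% in ~99.5% — the
qualitative pattern of the real pooled data (no deaths below 15 uM, a
steep rise above 20 uM). A shallower slope (steepness 5) leaks several
expected deaths below 15 uM and does not reproduce that pattern. The
truth is deliberately not fitted to any real cohort, keeping synthetic
and real data clearly separated; it is echoed alongside every generated
cohort so recovery tests can compare estimates with truth.

What the generator does not emulate: study-level heterogeneity (all
records carry one synthetic study id), assay error, censoring or
missingness, covariates (dose ingested, potassium, QRS width), and any
treatment-era effect. Passing tests on synthetic cohorts therefore
demonstrate the estimators' correctness under the assumed sampling
model, not the clinical conclusions one would draw from real data.

## Orchestration and reproducibility

`run_scenario()` and `run_poisoning()` bind the stages together:
validation strictly before computation (a bad config writes nothing),
every output bundle embedding the seed, an MD5 of the canonicalised
config, the package version and the parameter provenance. All
randomness flows through explicit integer seeds — the population spec's
seed for simulation, the bootstrap seed for CIs, one seed per synthetic
bundle — so reruns are bit-identical. There is no shell entry point:
the package is an analysis library, and these two functions plus the
configs are its orchestration surface.

Problem sizes used by the shipped checks are chosen to make the
statistical assertions sharp at small cost: 1e5 draws for
sampling-distribution recovery, 10,000 subjects for interval coverage
(±1% tolerance), 50,000-record cohorts for parameter recovery within
3 binomial SDs per bin, 200 replicates for the generator calibration,
and exhaustive enumeration (4^4 resamples) as the bootstrap oracle.

## Known limitations

No parameter estimation (simulation only); no PK/PD effect link — the
scaled EC50 values are overlay indicators with explicitly uncertain
in vivo relevance, not effect predictions; no QT/arrhythmia modelling;
no enantiomer- or metabolite-specific kinetics; and the shipped PK
values are illustrative stand-ins, so absolute simulated concentrations
should be interpreted as shape, not as reproductions of published
profiles.
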