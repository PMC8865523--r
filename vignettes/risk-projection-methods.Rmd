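---
title: "Methods: competing-risks projection of late mortality after mediastinal radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competing-risks projection of late mortality after mediastinal radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphrisk)
library(dplyr)
```

## What the package computes

`lymphrisk` projects the 30-year absolute mortality risk (AMR₃₀) from
cardiovascular disease (CVD) and second cancers for lymphoma patients
treated with thoracic radiotherapy, and decomposes it into what would have
happened anyway (background), what chemotherapy adds, and what each
radiation modality adds. The unit of analysis is a patient with paired
photon and proton plans on the same anatomy, so the modality contrast is a
within-patient dosimetric contrast: background and chemotherapy layers are
shared, and the photon−proton difference isolates radiation effects
exactly.

## The hazard model

For endpoint $c$, sex $s$, age at treatment $a$ and year $t = 1,\dots,H$
after treatment, the annual hazard is

$$h_c(t) = \lambda_c(s, a+t-1)\; \mathrm{RR}^{\text{smoke}}_c\;
\mathrm{RR}^{\text{chemo}}_c\; \bigl(1 + \mathrm{ERR}_c(a)\, D_c\bigr).$$

Assumptions, each chosen deliberately:

* **Piecewise-constant background rates.** $\lambda_c$ is looked up in
  half-open age bands $[\ell, u)$ exactly as national mortality tables
  tabulate it (deaths per 100,000 person-years ÷ 10⁵). No smoothing: a
  spline through tabulated rates would add unverifiable structure. One
  table per region is applied at all future attained ages; secular trends
  in mortality are deliberately not projected.
* **Linear no-threshold dose response in mean organ dose.** The radiation
  factor is $1 + \mathrm{ERR}\cdot D$ with no quadratic term and, by
  default, no latency (a configurable latency offset delays both treatment
  factors for sensitivity analyses). ERRs may be replaced within
  age-at-treatment bands — e.g. the bundled configuration uses a larger
  breast-cancer ERR below age 25, reflecting the higher radiosensitivity
  of young breast tissue.
* **Chemotherapy acts on cardiovascular endpoints only**, as an
  anthracycline rate ratio banded by cumulative mg/m²
  (doxorubicin-equivalent). Second cancers carry no chemotherapy excess.
* **Multiplicative combination by default.**
  $(1+\mathrm{ERR}\,D)\times\mathrm{RR}^{\text{chemo}}$; an additive-ERR
  mode ($1 + (\mathrm{RR}^{\text{chemo}}-1) + \mathrm{ERR}\,D$, floored at
  0) is available via `combination = "additive_err"` because the published
  evidence does not settle the interaction sharply. The mode in force is
  echoed into the output metadata.
* **Smoking multiplies everything** — background and both treatment
  excesses (full multiplicative transport). This is why the absolute
  benefit of sparing dose is larger in smokers: the same relative excess
  applies to a much larger base rate. Former smokers are pooled with
  current smokers by default (a separate `smoking_rr_former` is honored
  when configured); unknown status is treated as never-smoking, the
  conservative choice, and flagged in the decomposition output.
* **Treatment effects are constant over the horizon**: no waning with time
  since exposure.

The bundled `dose_response.json` ships *placeholder* coefficients of
plausible magnitude so that every pipeline stage is runnable and testable;
they are not estimates. In particular "other cardiac" disease
(pericardial disease, arrhythmias) has ERR = 0 — no published
dose–response exists for that residual group, and inventing one would be
worse than projecting it at background level. All package-level
correctness properties hold for any valid configuration.

## The life table

Cumulative risk uses a discrete annual cycle. Within year $t$ the total
hazard $H(t)$ is the sum of the competing hazards; the probability of
dying during the year is $S(t-1)\,(1-e^{-H(t)})$ with
$S(t)=e^{-\sum_{u\le t}H(u)}$, apportioned to cause $c$ in proportion
$h_c(t)/H(t)$. This exponential-within-year form was chosen over
$1-\prod(1-q)$ products because it is *exact* for constant competing
hazards — the package's life table reproduces
$\frac{h_c}{H}\left(1-e^{-HT}\right)$ to machine precision, which anchors
the test suite's oracles. A year with $H(t)=0$ contributes zero to every
cause (no 0/0). Negative hazards are rejected.

**Grouped competing-risks structure.** Each disease group is projected in
its own life table:

* the five cardiac/stroke endpoints (coronary heart disease, heart
  failure, valvular disease, other cardiac, stroke) are apportioned
  jointly — their modified rates sum to a single cardiovascular rate, and
  the CVD total is the sum of the five jointly-apportioned risks;
* each second cancer competes alone;
* in every table the competing hazard is the *all-cause background minus
  the group's own background*, floored at zero — competing mortality
  always enters at general-population level.

This structure has two consequences worth stating. First, the exactness
properties the package guarantees: with null exposure the full model
collapses to the background layer identically; a chemotherapy layer leaves
second-cancer risks untouched identically; and layer ordering
(background ≤ +chemo ≤ +chemo+RT) and dose monotonicity hold exactly for
every disease-group total and every second cancer. Second, a caveat:
*within* the joint cardiovascular table an endpoint whose own factor is
small (stroke under chemotherapy, other-cardiac under radiation) can see
its apportioned risk dip slightly when its competitors' hazards rise. That
is real competing-risks arithmetic, not a bug; the group totals are the
quantities to report.

Attained age in year $t$ is $a + t - 1$ (start-of-year lookup); with
5-year rate bands the alternative half-year offset changes nothing
band-visible, and a flag-free single convention keeps outputs
reproducible. A 30-year-old's projection therefore consults attained ages
30–59 only.

## Dosimetric subgroups and standardization

Patients are classified by anatomy alone: longitudinal CTV-to-heart
overlap (≥40% is inclusive, matching how the category is labelled in
clinical reports), CTV extension below the left main stem coronary artery
origin (a CTV ending exactly at the origin counts as "at and above
only"), extension below the T7 inferior endplate, and axillary
involvement. The overlap denominator is the **heart's** cranio-caudal
length: "≥40% overlap" then means "at least 40% of the heart lies in the
treated longitudinal band", which is the cardiac-dose rationale for the
criterion. Coordinates live on one patient axis with superior = larger;
only differences enter, so the labels are translation-invariant.

Subgroup risk summaries are directly standardized for age (10-year bands
by default) and sex, with the full input cohort as the default standard
population. When a positive-weight stratum is empty in a subgroup,
`standardize()` flags the row and returns `NA` rather than silently
renormalizing; the report path opts into renormalization explicitly
(small subgroups rarely cover every stratum) and carries the flag through.

## Dose-comparison statistics

Per-patient modality differences are tested with a one-sample *t* test
(two-sided); between-subgroup contrasts regress the per-patient difference
on the subgroup indicator with homoskedastic OLS — algebraically the
pooled-variance two-sample *t* test, which the suite verifies numerically
to 10⁻¹⁰ — with Welch inference behind a flag. No multiple-testing
adjustment is applied across organ metrics. Degenerate zero-variance
differences report a sentinel p-value of 10⁻¹⁵ rather than NaN.

## What the synthetic data emulate — and what they do not

`simulate_cohort()` draws a cohort with the structure of a real
proton-therapy planning study: 80 patients, 62.5% female, ages with median
≈30.5 (range 18–79), smoking 49/31/20% never/ever/unknown, subgroup
prevalences ≈29% (≥40% overlap), 82% (below-LMSCA), 59% (below-T7), 36%
(axilla), anthracycline median ≈340 mg/m² (range 170–420), and paired
photon/proton mean doses from truncated normals calibrated per subgroup to
published-table-like averages and ranges (protons spare the left
ventricle, valves, lungs, breast and integral normal tissue; carotid dose
is slightly higher with protons; within-patient photon–proton correlation
ρ = 0.7, a generator choice recorded in the truth sidecar). Subgroup
labels are drawn first and anatomy coordinates constructed to reproduce
them exactly, so the classifier and generator cannot drift apart.

`simulate_rate_tables()` builds Gompertz-like rates
$\lambda(x) = \lambda_0 e^{\beta x}$ per cause and sex in 5-year bands,
with region multipliers that order the cardiovascular burden Eastern
Europe > United States > Western Europe > Japan.

What passing tests on these data show: the engine's arithmetic is exact
where exactness is claimed, its orderings respond to dose and subgroup
structure as designed, and the full pipeline recovers the generator's
known truth. What they cannot show: calibration against real cohort
dosimetry or real national mortality — neither the patient-level dose data
nor the mortality extracts behind published analyses are public, so
absolute risk levels here are illustrative.

## Numerical and interface choices

* Half-open bands everywhere (ages, dose bands, age modifiers); boundary
  ages belong to the upper band.
* Region aggregation is an unweighted mean over member countries by
  default, with optional population weights; disagreeing band structures
  are first expanded losslessly to 1-year resolution under the
  piecewise-constant model.
* The competing-hazard floor at zero prevents double counting when modeled
  endpoints exceed the all-cause table (only possible with inconsistent
  user tables).
* `report.csv` rounds percentages to one decimal; `decomposition.csv`
  keeps full precision; metadata records the combination mode, standard
  population, configuration hash and smoking handling.
* All randomness sits behind one seed per generator call
  (`withr::with_seed`), so every CSV/JSON artifact is byte-reproducible.

The test suite sizes were chosen to keep the default run fast while
leaving no property under-sampled: 200 random schedules against the
monthly fine-grid oracle, 250 competing-hazard pairs, 25-point dose grids
per endpoint, 100 datasets for each statistics oracle, and 20 replicates
of 200 patients for end-to-end truth recovery.

## Known limitations

* Mortality only: the model does not project incidence, so quality-of-life
  endpoints and non-fatal events are out of scope.
* No proton RBE uncertainty: proton doses are taken as GyE at a fixed RBE
  of 1.1.
* No confidence intervals over patients (the config's `ci_low`/`ci_high`
  slots support coefficient-level sensitivity runs, not sampling error).
* No calendar-period effects or mortality forecasting.
* The placeholder coefficients bundled for testing must be replaced with
  literature values before any clinical interpretation.

## A minimal end-to-end run

```{r example, eval = FALSE}
cohort <- simulate_cohort(cohort_sim_spec(n_patients = 80, seed = 1))
rates <- simulate_rate_tables()
cfg <- load_config(system.file("extdata", "dose_response.json",
                               package = "lymphrisk"))
report <- cohort_report(cohort, rates, cfg)
report |>
  filter(disease_group == "cvd", subgroup == "overlap_ge40")
decomp <- decompose_cohort(cohort,
                           filter(rates, country == "united_states"), cfg)
autoplot(decomp)
```
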