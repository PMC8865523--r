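# lymphrisk

Projecting 30-year cause-specific mortality after radiotherapy for
mediastinal (supradiaphragmatic) lymphoma.

Modern involved-site radiotherapy cures most patients with Hodgkin
lymphoma, so the clinically decisive question has shifted to late effects:
deaths from radiation-induced cardiovascular disease (CVD) and second
cancers decades after treatment. Proton beam therapy (PBT) can spare the
heart, lungs and breast relative to even the best photon techniques, but it
is scarce and expensive, so referral decisions need a quantitative answer
to "how much mortality does the dose reduction actually buy, and for
whom?". `lymphrisk` is an R package for that calculation: it converts
per-patient mean organ and cardiac-substructure doses from paired
photon/proton plans into 30-year absolute mortality risks (AMR₃₀) under
competing risks, decomposed into background, chemotherapy-related and
radiation-related components, for the dosimetric subgroups used in
proton-referral guidelines. It is written for radiation oncologists,
medical physicists and radiation epidemiologists.

## The model

For endpoint *c* (coronary heart disease, heart failure, valvular heart
disease, other cardiac disease, stroke, lung/breast/esophageal cancer), a
patient of sex *s* treated at age *a* has annual hazard in year
*t* = 1…30 after treatment

```
h_c(t) = λ_c(s, a + t − 1) × RR_smoke(c) × RR_chemo(c) × (1 + ERR_c · D_c)
```

where `λ_c` is the attained-age, sex- and cause-specific background
mortality rate (per-100,000 tables, piecewise-constant in half-open age
bands), `RR_chemo` the anthracycline rate ratio (cardiovascular endpoints
only, banded by mg/m²), `RR_smoke` the current-smoker rate ratio, `ERR_c`
the excess relative risk per Gy (optionally replaced within
age-at-treatment bands) and `D_c` the mean dose to the endpoint's organ —
whole heart, left ventricle, the weighted valve summary
`SumValve = 0.553·AV + 0.368·MV + 0.079·TV`, carotid arteries, lungs,
breast or esophagus. Chemotherapy and radiation combine multiplicatively by
default (an additive-ERR mode is available); smoking multiplies both the
background and the treatment-related rates.

Cumulative risk uses a discrete annual life table with exponential
within-year survival and proportional cause apportionment: with total
hazard `H(t)` (the disease group's endpoints plus the residual background
hazard of all other causes),

```
AMR₃₀(c) = Σ_t  S(t−1) · (1 − e^(−H(t))) · h_c(t) / H(t),   S(t) = e^(−Σ_{u≤t} H(u))
```

The five cardiac/stroke endpoints are apportioned jointly in one
cardiovascular life table (their modified rates sum, as in the
epidemiological practice of treating CVD mortality as one competing
cause); each second cancer competes alone against the background of
everything else. Risks are computed in three cumulative layers —
background, +chemotherapy, +radiation per modality — whose differences are
the additive excess components, and subgroup summaries are directly
standardized for age and sex.

The bundled dose–response configuration
(`inst/extdata/dose_response.json`) carries illustrative placeholder
coefficients; substitute values from the primary dose–response literature
for substantive analyses.

## Worked example

```r
library(lymphrisk)
library(dplyr)

cohort <- simulate_cohort(cohort_sim_spec(n_patients = 80, seed = 1))
rates  <- simulate_rate_tables()              # 4 regions, Gompertz-like
cfg    <- load_config(system.file("extdata", "dose_response.json",
                                  package = "lymphrisk"))

us <- filter(rates, country == "united_states")
decomp <- decompose_cohort(cohort, us, cfg)
group_decomposition(decomp) |>
  group_by(disease_group) |>
  summarise(background = 100 * mean(amr30_background),
            chemo      = 100 * mean(amr30_chemo),
            photon     = 100 * mean(amr30_full_photon),
            proton     = 100 * mean(amr30_full_proton))
#> # A tibble: 4 × 5
#>   disease_group     background  chemo photon proton
#>   <chr>                  <dbl>  <dbl>  <dbl>  <dbl>
#> 1 breast_cancer         0.316  0.316   0.420  0.383
#> 2 cvd                   5.11   7.08   11.2   10.9
#> 3 esophageal_cancer     0.0788 0.0788  0.201  0.190
#> 4 lung_cancer           2.96   2.96    4.67   4.36

paired_difference_test(cohort, "left_ventricle")
#> Paired dose difference (proton minus photon), left_ventricle:
#>   n = 80, mean = -1.975 Gy (range -13.081 to 4.956), p = 1.16e-06
```

Reading the table: of this synthetic cohort's mean 11.2% 30-year CVD
mortality risk after chemotherapy and photon radiotherapy, 5.1 points are
background mortality, 2.0 points are added by anthracyclines and the rest
by radiation; replanning everyone with protons lowers the total to 10.9%.
The paired test shows protons spare the left ventricle by about 2 Gy on
average. `cohort_report()` produces the standardized
subgroup-by-region-by-modality table, `compare_doses()` the full
dosimetric comparison, `scenario_risk()` single-patient what-if panels
(e.g. smokers versus never-smokers at fixed subgroup-average doses), and
`autoplot()` on a decomposition draws the stacked layer figure.

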