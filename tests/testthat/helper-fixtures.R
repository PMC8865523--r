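suppressMessages({
  library(dplyr)
  library(tibble)
})

ALL_ENDPOINTS <- c(
  "coronary_heart_disease", "heart_failure", "valvular_heart_disease",
  "other_cardiac", "stroke", "lung_cancer", "breast_cancer",
  "esophageal_cancer"
)

# Flat two-band rate table for one country covering every endpoint and both
# sexes; per-cause rates settable via `rates` (named per-100k values applied
# to both bands) for targeted tests.
toy_rates <- function(country = "X",
                      causes = c(ALL_ENDPOINTS, "all_other_causes"),
                      rate_young = 50, rate_old = 500,
                      split_age = 50) {
  tidyr::expand_grid(
    country = country,
    sex = c("male", "female"),
    cause = causes,
    tibble(age_lo = c(0, split_age), age_hi = c(split_age, NA),
           rate_per_100k = c(rate_young, rate_old))
  ) |>
    lymphrisk::validate_rate_table()
}

# Minimal valid config built in code (no file round-trip).
toy_config <- function(overrides = list()) {
  base <- list(endpoints = list(
    coronary_heart_disease = list(dose_metric = "whole_heart",
                                  err_per_gy = 0.074,
                                  chemo_rr = list(list(dose_lo = 0, rr = 1.3)),
                                  smoking_rr = 2.2),
    heart_failure = list(dose_metric = "left_ventricle", err_per_gy = 0.10,
                         chemo_rr = list(
                           list(dose_lo = 0, dose_hi = 250, rr = 1.7),
                           list(dose_lo = 250, rr = 2.6)
                         ),
                         smoking_rr = 1.6),
    valvular_heart_disease = list(dose_metric = "sum_valve",
                                  err_per_gy = 0.05,
                                  chemo_rr = list(list(dose_lo = 0, rr = 1.4))),
    other_cardiac = list(dose_metric = "whole_heart", err_per_gy = 0,
                         chemo_rr = list(list(dose_lo = 0, rr = 1.3)),
                         smoking_rr = 1.5),
    stroke = list(dose_metric = "carotid_arteries", err_per_gy = 0.05,
                  smoking_rr = 1.9),
    lung_cancer = list(dose_metric = "lungs", err_per_gy = 0.10,
                       smoking_rr = 14),
    breast_cancer = list(dose_metric = "breast", err_per_gy = 0.05,
                         age_modifiers = list(
                           list(age_lo = 0, age_hi = 25, err_per_gy = 0.30),
                           list(age_lo = 25, age_hi = 35, err_per_gy = 0.15)
                         )),
    esophageal_cancer = list(dose_metric = "esophagus", err_per_gy = 0.10)
  ))
  for (nm in names(overrides)) base$endpoints[[nm]] <- overrides[[nm]]
  lymphrisk::validate_config(base)
}

# Hand-built cohort row; defaults give a quiet female never-smoker.
toy_patient_row <- function(id = "p1", modality = "photon", sex = "female",
                            age = 30, smoking = "never", anthra = 0,
                            dose = 0, breast = dose,
                            ctv_sup = 18, ctv_inf = 6, heart_sup = 12,
                            heart_inf = 0, lmsca_z = 10, t7_z = 8,
                            axilla = FALSE, ...) {
  dots <- list(...)
  row <- tibble(
    id = id, sex = sex, age = age, smoking = smoking,
    anthracycline_mg_m2 = anthra, modality = modality,
    whole_heart = dose, left_ventricle = dose, aortic_valve = dose,
    mitral_valve = dose, tricuspid_valve = dose, carotid_arteries = dose,
    lungs = dose, breast = breast, esophagus = dose, normal_tissue = dose,
    ctv_sup = ctv_sup, ctv_inf = ctv_inf, heart_sup = heart_sup,
    heart_inf = heart_inf, lmsca_z = lmsca_z, t7_z = t7_z, axilla = axilla
  )
  for (nm in names(dots)) row[[nm]] <- dots[[nm]]
  row
}

toy_patient <- function(id = "p1", dose_photon = 5, dose_proton = 2, ...) {
  bind_rows(
    toy_patient_row(id = id, modality = "photon", dose = dose_photon, ...),
    toy_patient_row(id = id, modality = "proton", dose = dose_proton, ...)
  )
}

# Independent fine-grid oracle: monthly competing-risks accumulation with
# exponential within-month survival, written as a plain loop. `haz` is a
# years x causes matrix of annual hazards.
monthly_amr_oracle <- function(haz, steps_per_year = 12) {
  n_causes <- ncol(haz)
  amr <- numeric(n_causes)
  S <- 1
  for (t in seq_len(nrow(haz))) {
    H_year <- sum(haz[t, ])
    for (m in seq_len(steps_per_year)) {
      H <- H_year / steps_per_year
      if (H > 0) {
        p_die <- S * (1 - exp(-H))
        amr <- amr + p_die * haz[t, ] / H_year
        S <- S * exp(-H)
      }
    }
  }
  amr
}

# Schedule tibble from a years x causes hazard matrix.
schedule_from_matrix <- function(haz, causes = colnames(haz)) {
  tidyr::expand_grid(year = seq_len(nrow(haz)), cause = causes) |>
    mutate(hazard = as.vector(t(haz)))
}

us_rates <- function() {
  dplyr::filter(lymphrisk::simulate_rate_tables(), country == "united_states")
}
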