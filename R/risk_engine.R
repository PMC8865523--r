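#' Build a per-endpoint annual hazard schedule for one patient
#'
#' For each future year `t = 1..horizon` and each modeled endpoint, the
#' annual hazard is the background cause-specific hazard at the attained age
#' `age + t - 1` (start-of-year lookup) multiplied by the applicable rate
#' factors for the requested layer:
#'
#' * `"background"`: background x smoking factor;
#' * `"chemo"`: background x smoking x anthracycline factor;
#' * `"full"`: background x smoking x anthracycline x radiation factors
#'   (the latter from the requested modality's dose summary).
#'
#' The competing `all_other_causes` hazard is the all-cause background hazard
#' minus the modeled endpoints' background hazards, floored at zero, and is
#' identical across layers. With `combination = "additive_err"`, the
#' chemotherapy and radiation excesses add on the excess-relative-risk scale
#' (`1 + (RR_chemo - 1) + (ERR x D)`) instead of multiplying; smoking
#' multiplies the whole rate in both modes.
#'
#' @param patient A one-patient slice of a cohort tibble (one row per
#'   modality).
#' @param rates A rate table for a single region.
#' @param cfg A `lymphrisk_config`.
#' @param layer `"background"`, `"chemo"` or `"full"`.
#' @param modality `"photon"` or `"proton"` (needed for `layer = "full"`).
#' @param horizon Projection horizon, years (default 30).
#' @param combination `"multiplicative"` (default) or `"additive_err"`.
#' @param latency Years after treatment before radiation and chemotherapy
#'   excesses apply (default 0).
#' @return A tibble with columns `year`, `cause`, `hazard` (per person-year),
#'   covering the modeled endpoints plus `all_other_causes`.
#' @export
build_hazard_schedule <- function(patient, rates, cfg,
                                  layer = c("full", "background", "chemo"),
                                  modality = "photon", horizon = 30,
                                  combination = c("multiplicative", "additive_err"),
                                  latency = 0) {
  layer <- match.arg(layer)
  combination <- match.arg(combination)
  stopifnot(nrow(patient) >= 1)
  haz <- cohort_hazards(patient, rates, cfg, horizon = horizon,
                        combination = combination, latency = latency)
  col <- switch(layer,
    background = "h_background",
    chemo = "h_chemo",
    full = paste0("h_full_", match.arg(modality, c("photon", "proton")))
  )
  haz |>
    transmute(.data$year, .data$cause, hazard = .data[[col]])
}

#' Cause-specific cumulative mortality under competing risks
#'
#' Discrete annual life table with exponential within-year survival and
#' proportional cause apportionment. Within year `t` the total hazard is
#' `H(t) = sum over causes h_c(t)`; the probability of dying during year `t`
#' is `S(t-1) * (1 - exp(-H(t)))`, apportioned to cause `c` as
#' `h_c(t) / H(t)`, with `S(t) = exp(-sum_{u<=t} H(u))`. The cause-specific
#' 30-year absolute mortality risk (AMR30) is the sum of these yearly
#' contributions.
#'
#' @param schedule A tibble with columns `year` (1..horizon), `cause`,
#'   `hazard` (annual, per person-year), covering every competing cause.
#' @param cause Optional single cause; when given, returns a scalar.
#' @param horizon Years to accumulate (default 30; must be covered by
#'   `schedule`).
#' @return A tibble with columns `cause` and `amr` (cumulative probability in
#'   `[0, 1]`), or a scalar if `cause` is given.
#' @examples
#' sched <- tidyr::expand_grid(year = 1:30, cause = c("a", "other"))
#' sched$hazard <- 0.01
#' cumulative_mortality(sched, cause = "a") # 0.5 * (1 - exp(-0.6))
#' @export
cumulative_mortality <- function(schedule, cause = NULL, horizon = 30) {
  if (any(schedule$hazard < 0)) {
    abort("negative hazard in schedule", class = "lymphrisk_validation_error")
  }
  if (max(schedule$year) < horizon) {
    abort("schedule does not cover the requested horizon",
          class = "lymphrisk_validation_error")
  }
  sched <- filter(schedule, .data$year <= horizon)
  out <- amr_from_long(mutate(sched, id = 1L), "hazard") |>
    select(all_of(c("cause", "amr")))
  if (!is.null(cause)) {
    return(out$amr[out$cause == cause])
  }
  out
}

# Vectorized life table over a long tibble with columns id, year, cause and
# one hazard column named by `col`. Returns id x cause AMRs. Years with zero
# total hazard contribute zero to every cause (no 0/0 division).
amr_from_long <- function(df, col) {
  tot <- df |>
    group_by(.data$id, .data$year) |>
    summarise(H = sum(.data[[col]]), .groups = "drop") |>
    arrange(.data$id, .data$year) |>
    group_by(.data$id) |>
    mutate(
      S_prev = exp(-(cumsum(.data$H) - .data$H)),
      p_die = .data$S_prev * (1 - exp(-.data$H))
    ) |>
    ungroup()
  df |>
    inner_join(select(tot, all_of(c("id", "year", "H", "p_die"))),
               by = c("id", "year")) |>
    mutate(q = if_else(.data$H > 0, .data[[col]] / .data$H * .data$p_die, 0)) |>
    group_by(.data$id, .data$cause) |>
    summarise(amr = sum(.data$q), .groups = "drop")
}

# Per-patient scalar rate factors for every endpoint: smoking, chemo and
# radiation (per modality), from the config. Returns a tibble
# id x endpoint with factor columns.
patient_factors <- function(patients, doses_wide, cfg) {
  grid <- tidyr::expand_grid(
    id = patients$id, endpoint = MODELED_ENDPOINTS
  ) |>
    left_join(patients, by = "id")

  fsmoke <- mapply(function(ep, st) smoking_rate_factor(cfg, ep, st),
                   grid$endpoint, grid$smoking)
  fchemo <- mapply(function(ep, d) chemo_rate_factor(cfg, ep, d),
                   grid$endpoint, grid$anthracycline_mg_m2)

  dose_lookup <- split(
    doses_wide[, c(DOSE_METRICS, "sum_valve")],
    paste(doses_wide$id, doses_wide$modality, sep = "\r")
  )
  sex_of <- setNames(patients$sex, patients$id)
  age_of <- setNames(patients$age, patients$id)
  rad_one <- function(ep, id, modality) {
    dl <- as.list(dose_lookup[[paste(id, modality, sep = "\r")]][1, ])
    # absent breast dose: zero dose for males (background-only endpoint),
    # error for females
    if (ep == "breast_cancer" && is.na(dl$breast)) {
      if (sex_of[[id]] == "male") return(1)
      abort(sprintf("patient '%s': female record lacks a breast dose", id),
            class = "lymphrisk_validation_error")
    }
    radiation_rate_factor(cfg, ep, dl, age_of[[id]])
  }
  frad_ph <- mapply(rad_one, grid$endpoint, grid$id,
                    MoreArgs = list(modality = "photon"))
  frad_pr <- mapply(rad_one, grid$endpoint, grid$id,
                    MoreArgs = list(modality = "proton"))

  grid |>
    transmute(.data$id, .data$endpoint,
              f_smoke = unname(fsmoke), f_chemo = unname(fchemo),
              f_rad_photon = unname(frad_ph), f_rad_proton = unname(frad_pr))
}

# Patient-level fields, dose summaries and modality checks for a cohort.
cohort_components <- function(cohort) {
  cohort <- validate_cohort(cohort)
  patients <- cohort |>
    distinct(.data$id, .data$sex, .data$age, .data$smoking,
             .data$anthracycline_mg_m2)
  if (any(duplicated(patients$id))) {
    abort("inconsistent patient-level fields across modality rows",
          class = "lymphrisk_validation_error")
  }
  doses_wide <- cohort |>
    mutate(sum_valve = sum_valve_dose(.data$aortic_valve, .data$mitral_valve,
                                      .data$tricuspid_valve)) |>
    select(all_of(c("id", "modality", DOSE_METRICS, "sum_valve")))
  for (m in c("photon", "proton")) {
    miss <- setdiff(patients$id, doses_wide$id[doses_wide$modality == m])
    if (length(miss) > 0) {
      abort(sprintf("patient '%s' lacks a %s dose summary", miss[[1]], m),
            class = "lymphrisk_validation_error")
    }
  }
  list(patients = patients, doses_wide = doses_wide)
}

# Background hazard grid: one row per (id, year, cause) for every cause in
# the rate table, with the attained-age lookup age + year - 1 (start of
# year). The open-ended top band covers every attained age, so coverage can
# only fail if a (sex, cause) series is missing; hazard() reports that.
background_grid <- function(patients, rates, horizon) {
  grid <- tidyr::expand_grid(
    id = patients$id, year = seq_len(horizon)
  ) |>
    left_join(patients, by = "id") |>
    mutate(attained_age = .data$age + .data$year - 1)
  tidyr::expand_grid(
    grid |> select(all_of(c("id", "year", "sex", "attained_age"))),
    cause = unique(rates$cause)
  ) |>
    mutate(h_bg = hazard(rates, .data$sex, .data$cause, .data$attained_age))
}

# Long hazard tibble: one row per (id, year, cause) for the requested
# endpoints plus the competing all_other_causes hazard, with layer columns
# h_background, h_chemo, h_full_photon, h_full_proton. The competing hazard
# is the all-cause background minus the requested endpoints' background
# (floored at 0): every cause outside `endpoints` competes at its
# unmodified background level, and is identical across layers.
cohort_hazards <- function(cohort, rates, cfg, horizon = 30,
                           combination = "multiplicative", latency = 0,
                           endpoints = MODELED_ENDPOINTS,
                           bg = NULL, factors = NULL) {
  comp <- cohort_components(cohort)
  patients <- comp$patients
  bg <- bg %||% background_grid(patients, rates, horizon)
  factors <- factors %||% patient_factors(patients, comp$doses_wide, cfg)

  other <- bg |>
    group_by(.data$id, .data$year) |>
    summarise(
      h_other = pmax(
        sum(.data$h_bg) - sum(.data$h_bg[.data$cause %in% endpoints]), 0
      ),
      .groups = "drop"
    ) |>
    mutate(cause = OTHER_CAUSE,
           h_background = .data$h_other, h_chemo = .data$h_other,
           h_full_photon = .data$h_other, h_full_proton = .data$h_other) |>
    select(-"h_other")

  lagged <- function(f, year) if_else(year > latency, f, 1)
  modeled <- bg |>
    filter(.data$cause %in% endpoints) |>
    inner_join(factors, by = c("id", "cause" = "endpoint")) |>
    mutate(
      f_chemo_t = lagged(.data$f_chemo, .data$year),
      f_rad_ph_t = lagged(.data$f_rad_photon, .data$year),
      f_rad_pr_t = lagged(.data$f_rad_proton, .data$year),
      h_background = .data$h_bg * .data$f_smoke,
      h_chemo = .data$h_background * .data$f_chemo_t,
      h_full_photon = .data$h_background * combine_excess(
        .data$f_chemo_t, .data$f_rad_ph_t, combination),
      h_full_proton = .data$h_background * combine_excess(
        .data$f_chemo_t, .data$f_rad_pr_t, combination)
    ) |>
    select(all_of(c("id", "year", "cause", "h_background", "h_chemo",
                    "h_full_photon", "h_full_proton")))

  bind_rows(modeled, select(other, all_of(names(modeled)))) |>
    arrange(.data$id, .data$year, .data$cause)
}

# Combine chemotherapy and radiation rate factors: multiplicatively (default)
# or additively on the excess-relative-risk scale, floored at 0.
combine_excess <- function(f_chemo, f_rad, combination) {
  if (combination == "multiplicative") {
    f_chemo * f_rad
  } else {
    pmax(1 + (f_chemo - 1) + (f_rad - 1), 0)
  }
}

#' Decompose 30-year mortality risk for every patient and endpoint
#'
#' Runs the competing-risks life table for three cumulative layers
#' (background incl. smoking; + chemotherapy; + radiation per modality) and
#' differences them into additive components. Each disease group is
#' projected in its own life table: the five cardiac/stroke endpoints are
#' jointly apportioned within the cardiovascular table (their modified
#' rates sum, as a single cardiovascular rate, against the competing
#' background of all other causes), and each second cancer competes alone
#' against the background of everything else. Competing mortality always
#' enters at its unmodified background level, so a layer or dose change for
#' one endpoint never perturbs another group's risk.
#'
#' @param cohort A cohort tibble (both modalities per patient).
#' @param rates A rate table for one region.
#' @param cfg A `lymphrisk_config`.
#' @inheritParams build_hazard_schedule
#' @return A tibble classed `lymphrisk_decomposition`: one row per (patient,
#'   endpoint) with `amr30_background`, `amr30_chemo`, `amr30_full_photon`,
#'   `amr30_full_proton`, `excess_chemo`, `excess_rt_photon`,
#'   `excess_rt_proton`, and `smoking_assumed_never` (TRUE where an unknown
#'   smoking status was treated as never-smoking). Attributes record the
#'   horizon, combination mode and region.
#' @export
decompose_cohort <- function(cohort, rates, cfg, horizon = 30,
                             combination = c("multiplicative", "additive_err"),
                             latency = 0) {
  combination <- match.arg(combination)
  comp <- cohort_components(cohort)
  bg <- background_grid(comp$patients, rates, horizon)
  factors <- patient_factors(comp$patients, comp$doses_wide, cfg)

  # each disease group gets its own life table: the group's endpoints carry
  # the treatment factors and compete against the unmodified background of
  # everything else. The five cardiac/stroke causes are jointly apportioned
  # within the cardiovascular table; each second cancer stands alone.
  groups <- c(list(cvd = CVD_ENDPOINTS), setNames(as.list(SC_ENDPOINTS),
                                                  SC_ENDPOINTS))
  one_layer <- function(haz, col, name) {
    amr_from_long(haz, col) |>
      rename(!!name := "amr")
  }
  out <- purrr::map_dfr(groups, function(eps) {
    haz <- cohort_hazards(cohort, rates, cfg, horizon = horizon,
                          combination = combination, latency = latency,
                          endpoints = eps, bg = bg, factors = factors)
    one_layer(haz, "h_background", "amr30_background") |>
      inner_join(one_layer(haz, "h_chemo", "amr30_chemo"),
                 by = c("id", "cause")) |>
      inner_join(one_layer(haz, "h_full_photon", "amr30_full_photon"),
                 by = c("id", "cause")) |>
      inner_join(one_layer(haz, "h_full_proton", "amr30_full_proton"),
                 by = c("id", "cause")) |>
      filter(.data$cause != OTHER_CAUSE)
  }) |>
    rename(endpoint = "cause") |>
    mutate(
      excess_chemo = .data$amr30_chemo - .data$amr30_background,
      excess_rt_photon = .data$amr30_full_photon - .data$amr30_chemo,
      excess_rt_proton = .data$amr30_full_proton - .data$amr30_chemo
    ) |>
    left_join(
      cohort |> distinct(.data$id, .data$smoking) |>
        transmute(.data$id, smoking_assumed_never = .data$smoking == "unknown"),
      by = "id"
    ) |>
    arrange(.data$id, match(.data$endpoint, MODELED_ENDPOINTS))
  structure(out,
    class = c("lymphrisk_decomposition", class(out)),
    horizon = horizon, combination = combination, latency = latency,
    region = unique(rates$country)
  )
}

#' @rdname decompose_cohort
#' @param patient A one-patient cohort slice (both modality rows).
#' @export
decompose_patient <- function(patient, rates, cfg, ...) {
  decompose_cohort(patient, rates, cfg, ...)
}

#' Collapse an endpoint-level decomposition to disease groups
#'
#' Sums the five cardiac/stroke endpoints into a `cvd` group; second cancers
#' pass through as their own groups. The five cardiac risks come from one
#' joint life table ([decompose_cohort()]), so their sum is the cumulative
#' incidence of the pooled cardiovascular cause.
#'
#' @param decomp A `lymphrisk_decomposition`.
#' @return A tibble with `disease_group` in
#'   `c("cvd", "lung_cancer", "breast_cancer", "esophageal_cancer")`.
#' @export
group_decomposition <- function(decomp) {
  val_cols <- c("amr30_background", "amr30_chemo", "amr30_full_photon",
                "amr30_full_proton", "excess_chemo", "excess_rt_photon",
                "excess_rt_proton")
  decomp |>
    mutate(disease_group = if_else(.data$endpoint %in% CVD_ENDPOINTS,
                                   "cvd", .data$endpoint)) |>
    group_by(.data$id, .data$disease_group) |>
    summarise(across(all_of(val_cols), sum), .groups = "drop")
}

#' Project risk for a hypothetical exposure scenario
#'
#' Builds a single synthetic patient record from explicit doses and exposure
#' and runs [decompose_patient()] on it; used for what-if panels such as
#' smoker versus never-smoker comparisons at fixed subgroup-average doses.
#'
#' @param age,sex,smoking Patient profile.
#' @param doses_photon,doses_proton Named numeric vectors with the dose
#'   metric columns (`whole_heart`, `left_ventricle`, `aortic_valve`,
#'   `mitral_valve`, `tricuspid_valve`, `carotid_arteries`, `lungs`,
#'   `breast`, `esophagus`, `normal_tissue`); omitted metrics default to 0
#'   (breast stays NA for males).
#' @param anthracycline Dose in mg/m^2.
#' @param rates,cfg As in [decompose_cohort()].
#' @param ... Passed to [decompose_cohort()].
#' @return A `lymphrisk_decomposition` with one patient.
#' @export
scenario_risk <- function(age, sex, smoking, doses_photon, doses_proton,
                          anthracycline, rates, cfg, ...) {
  fill <- function(d) {
    base <- setNames(rep(0, length(DOSE_METRICS)), DOSE_METRICS)
    if (sex == "male") base["breast"] <- NA_real_
    base[names(d)] <- d
    base
  }
  row <- function(modality, d) {
    as_tibble(c(
      list(id = "scenario", sex = sex, age = age, smoking = smoking,
           anthracycline_mg_m2 = anthracycline, modality = modality),
      as.list(fill(d)),
      list(ctv_sup = 1, ctv_inf = 0, heart_sup = 1, heart_inf = 0,
           lmsca_z = 0.5, t7_z = 0.5, axilla = FALSE)
    ))
  }
  patient <- bind_rows(row("photon", doses_photon), row("proton", doses_proton))
  decompose_patient(patient, rates, cfg, ...)
}
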