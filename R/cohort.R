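#' @name cohort-schema
#' @title Cohort table schema
#' @description
#' A cohort is a tibble with one row per (patient, modality). Columns:
#' `id`, `sex` ("male"/"female"), `age` (years at treatment), `smoking`
#' ("never", "current", "former", "unknown"), `anthracycline_mg_m2`
#' (doxorubicin-equivalent mg/m^2), `modality` ("photon"/"proton"), mean
#' doses in Gy (protons: GyE at RBE 1.1) `whole_heart`, `left_ventricle`,
#' `aortic_valve`, `mitral_valve`, `tricuspid_valve`, `carotid_arteries`
#' (mean of left+right common carotid), `lungs`, `breast` (female only,
#' optional: NA allowed), `esophagus`, `normal_tissue` (body minus PTV), and
#' anatomy on a single cranio-caudal axis (cm, superior = larger): `ctv_sup`,
#' `ctv_inf`, `heart_sup`, `heart_inf`, `lmsca_z` (origin of the left main
#' stem coronary artery), `t7_z` (inferior endplate of the 7th thoracic
#' vertebra), `axilla` (logical).
NULL

COHORT_COLUMNS <- c(
  "id", "sex", "age", "smoking", "anthracycline_mg_m2", "modality",
  DOSE_METRICS,
  "ctv_sup", "ctv_inf", "heart_sup", "heart_inf", "lmsca_z", "t7_z", "axilla"
)

#' Validate a cohort table
#'
#' Checks the cohort schema (see [cohort-schema]): required columns, paired
#' unique (id, modality) rows, non-negative ages, anthracycline doses and
#' organ doses, a configurable sanity cap on doses, and superior > inferior
#' for each anatomical extent.
#'
#' @param cohort A cohort tibble.
#' @param dose_cap Sanity cap on any mean dose, Gy (default 60).
#' @return The cohort, invisibly classed `lymphrisk_cohort`.
#' @export
validate_cohort <- function(cohort, dose_cap = 60) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort is missing required column '%s'", missing_cols[[1]]),
          class = "lymphrisk_schema_error")
  }
  dup <- cohort |> count(.data$id, .data$modality) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate rows for patient '%s', modality '%s'",
                  dup$id[1], dup$modality[1]),
          class = "lymphrisk_validation_error")
  }
  if (any(!cohort$sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'", class = "lymphrisk_validation_error")
  }
  if (any(!cohort$smoking %in% c("never", "current", "former", "unknown"))) {
    abort("smoking must be never/current/former/unknown",
          class = "lymphrisk_validation_error")
  }
  if (any(cohort$age < 0) || any(cohort$anthracycline_mg_m2 < 0)) {
    abort("age and anthracycline_mg_m2 must be >= 0",
          class = "lymphrisk_validation_error")
  }
  doses <- as.matrix(cohort[, DOSE_METRICS])
  if (any(doses < 0, na.rm = TRUE)) {
    abort("doses must be >= 0", class = "lymphrisk_validation_error")
  }
  if (any(doses > dose_cap, na.rm = TRUE)) {
    abort(sprintf("dose exceeds the %g Gy sanity cap", dose_cap),
          class = "lymphrisk_validation_error")
  }
  # breast dose is optional only for female patients without one; other
  # metrics must be present
  core <- setdiff(DOSE_METRICS, "breast")
  if (any(is.na(as.matrix(cohort[, core])))) {
    abort("missing (NA) dose for a required metric",
          class = "lymphrisk_validation_error")
  }
  if (any(cohort$ctv_sup <= cohort$ctv_inf) ||
      any(cohort$heart_sup <= cohort$heart_inf)) {
    abort("superior coordinate must exceed inferior for CTV and heart extents",
          class = "lymphrisk_validation_error")
  }
  class(cohort) <- unique(c("lymphrisk_cohort", class(cohort)))
  cohort
}

#' Read / write a cohort CSV
#'
#' Round-trips the cohort schema losslessly; `smoking = "unknown"` is
#' preserved as the literal string.
#'
#' @param path CSV file path.
#' @return `read_cohort()`: a validated cohort tibble.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(), sex = readr::col_character(),
      smoking = readr::col_character(), modality = readr::col_character(),
      axilla = readr::col_logical(), .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_cohort(as_tibble(raw))
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort[, COHORT_COLUMNS], path)
  invisible(path)
}

#' Summary dose to the heart valves
#'
#' Weighted average of the mean aortic, mitral and tricuspid valve doses,
#' `0.553 * AV + 0.368 * MV + 0.079 * TV`, used as the dose metric for
#' valvular heart disease. Vectorized.
#'
#' @param aortic_valve,mitral_valve,tricuspid_valve Mean doses, Gy.
#' @return Numeric vector of SumValve doses, Gy.
#' @examples
#' sum_valve_dose(10, 10, 10) # 10
#' sum_valve_dose(10, 0, 0)   # 5.53
#' @export
sum_valve_dose <- function(aortic_valve, mitral_valve, tricuspid_valve) {
  for (nm in c("aortic_valve", "mitral_valve", "tricuspid_valve")) {
    v <- get(nm)
    if (any(is.na(v))) {
      abort(sprintf("missing %s dose", nm), class = "lymphrisk_validation_error")
    }
  }
  0.553 * aortic_valve + 0.368 * mitral_valve + 0.079 * tricuspid_valve
}

#' Longitudinal CTV-to-heart overlap fraction
#'
#' Length of the intersection of the CTV and heart cranio-caudal extents,
#' divided by the heart's cranio-caudal length, clipped to [0, 1]. Only
#' coordinate differences matter, so the result is invariant to a common
#' translation of all z coordinates. Vectorized.
#'
#' @param ctv_sup,ctv_inf,heart_sup,heart_inf Extent coordinates (cm,
#'   superior = larger value).
#' @return Overlap fractions in [0, 1].
#' @examples
#' heart_overlap_fraction(20, 0, 5, -10) # 5/15
#' @export
heart_overlap_fraction <- function(ctv_sup, ctv_inf, heart_sup, heart_inf) {
  heart_len <- heart_sup - heart_inf
  if (any(heart_len <= 0)) {
    abort("degenerate heart extent (zero or negative length)",
          class = "lymphrisk_validation_error")
  }
  inter <- pmin(ctv_sup, heart_sup) - pmax(ctv_inf, heart_inf)
  pmin(pmax(inter / heart_len, 0), 1)
}

#' Classify patients into dosimetric subgroups
#'
#' Adds the four subgroup labels used in reporting, derived from anatomy
#' only (dose values are never consulted):
#'
#' * `overlap`: `"ge40"` iff [heart_overlap_fraction()] >= `overlap_threshold`
#'   (inclusive), else `"lt40"`;
#' * `lmsca`: `"below"` iff the CTV's inferior edge extends strictly below
#'   the origin of the left main stem coronary artery, else `"above_only"`
#'   (a CTV ending exactly at the origin is "at and above only");
#' * `t7`: `"below"` iff the CTV extends strictly below the inferior
#'   endplate of the 7th thoracic vertebra, else `"above"`;
#' * `axilla`: `"yes"`/`"no"`.
#'
#' @param cohort A cohort tibble (one or two rows per patient; anatomy is
#'   per-patient, so labels repeat across modalities).
#' @param overlap_threshold Overlap fraction threshold (default 0.40).
#' @return The cohort with columns `overlap_fraction`, `overlap`, `lmsca`,
#'   `t7`, `axilla_group` appended.
#' @export
classify_subgroups <- function(cohort, overlap_threshold = 0.40) {
  cohort |>
    mutate(
      overlap_fraction = heart_overlap_fraction(
        .data$ctv_sup, .data$ctv_inf, .data$heart_sup, .data$heart_inf
      ),
      overlap = if_else(.data$overlap_fraction >= overlap_threshold,
                        "ge40", "lt40"),
      lmsca = if_else(.data$ctv_inf < .data$lmsca_z, "below", "above_only"),
      t7 = if_else(.data$ctv_inf < .data$t7_z, "below", "above"),
      axilla_group = if_else(.data$axilla, "yes", "no")
    )
}
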