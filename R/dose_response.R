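DOSE_METRIC_CHOICES <- c(
  "whole_heart", "left_ventricle", "sum_valve", "carotid_arteries",
  "lungs", "breast", "esophagus", "normal_tissue"
)

#' Load a dose-response coefficient configuration
#'
#' Reads a JSON configuration mapping each modeled endpoint to a dose metric,
#' an excess relative risk (ERR) per Gy (optionally replaced within
#' age-at-treatment bands), anthracycline rate-ratio bands (mg/m^2), and a
#' current-smoker rate ratio. The bundled file
#' `system.file("extdata", "dose_response.json", package = "lymphrisk")`
#' carries illustrative placeholder coefficients; users reproducing published
#' analyses should supply values from the primary dose-response literature.
#'
#' @param path JSON file path.
#' @param dose_cap Sanity dose range upper end, Gy; ERRs must keep
#'   `1 + ERR * dose > 0` on `[0, dose_cap]`.
#' @return A `lymphrisk_config` list with one entry per endpoint.
#' @export
load_config <- function(path, dose_cap = 60) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$endpoints)) {
    abort("config must have a top-level 'endpoints' object",
          class = "lymphrisk_schema_error")
  }
  validate_config(raw, dose_cap = dose_cap)
}

#' @rdname load_config
#' @param cfg A config list (as parsed from JSON) to validate.
#' @export
validate_config <- function(cfg, dose_cap = 60) {
  eps <- cfg$endpoints
  missing_ep <- setdiff(MODELED_ENDPOINTS, names(eps))
  if (length(missing_ep) > 0) {
    abort(sprintf("config missing endpoint '%s'", missing_ep[[1]]),
          class = "lymphrisk_validation_error")
  }
  for (ep in names(eps)) {
    e <- eps[[ep]]
    if (is.null(e$dose_metric) || !e$dose_metric %in% DOSE_METRIC_CHOICES) {
      abort(sprintf("endpoint '%s' has unknown dose metric '%s'",
                    ep, e$dose_metric %||% "<missing>"),
            class = "lymphrisk_schema_error")
    }
    errs <- as.numeric(e$err_per_gy %||% 0)
    mods <- e$age_modifiers %||% list()
    if (length(mods) > 0) {
      lo <- vapply(mods, function(m) as.numeric(m$age_lo), 0)
      hi <- vapply(mods, function(m) {
        if (is.null(m$age_hi)) Inf else as.numeric(m$age_hi)
      }, 0)
      ord <- order(lo)
      lo <- lo[ord]; hi <- hi[ord]
      if (any(hi[-length(hi)] > lo[-1])) {
        abort(sprintf("endpoint '%s': overlapping age-modifier bands", ep),
              class = "lymphrisk_validation_error")
      }
      errs <- c(errs, vapply(mods, function(m) {
        if (!is.null(m$err_per_gy)) as.numeric(m$err_per_gy)
        else as.numeric(e$err_per_gy %||% 0) * as.numeric(m$multiplier)
      }, 0))
    }
    if (any(1 + errs * dose_cap <= 0)) {
      abort(sprintf(
        "endpoint '%s': ERR %.4g drives the rate factor below 0 within the %g Gy sanity range",
        ep, min(errs), dose_cap
      ), class = "lymphrisk_validation_error")
    }
    for (b in e$chemo_rr %||% list()) {
      if (as.numeric(b$rr) <= 0) {
        abort(sprintf("endpoint '%s': chemo rate ratio must be > 0", ep),
              class = "lymphrisk_validation_error")
      }
    }
    if (!is.null(e$smoking_rr) && as.numeric(e$smoking_rr) <= 0) {
      abort(sprintf("endpoint '%s': smoking rate ratio must be > 0", ep),
            class = "lymphrisk_validation_error")
    }
  }
  structure(cfg, class = "lymphrisk_config")
}

# ERR per Gy applicable at a given age at treatment: the age-modifier band
# containing the age replaces (or scales) the base ERR; outside all bands the
# base ERR applies.
err_at_age <- function(endpoint_cfg, age_at_treatment) {
  base <- as.numeric(endpoint_cfg$err_per_gy %||% 0)
  for (m in endpoint_cfg$age_modifiers %||% list()) {
    lo <- as.numeric(m$age_lo)
    hi <- if (is.null(m$age_hi)) Inf else as.numeric(m$age_hi)
    if (age_at_treatment >= lo && age_at_treatment < hi) {
      if (!is.null(m$err_per_gy)) return(as.numeric(m$err_per_gy))
      return(base * as.numeric(m$multiplier))
    }
  }
  base
}

#' Radiation rate factor for one endpoint
#'
#' Returns `1 + ERR(age) * D`: the multiplicative factor applied to the
#' endpoint's background mortality rate, where `D` is the mean dose to the
#' endpoint's configured metric and `ERR(age)` is the excess relative risk
#' per Gy after applying any age-at-treatment modifier band.
#'
#' @param cfg A `lymphrisk_config`.
#' @param endpoint Endpoint identifier.
#' @param doses Named list/vector of dose metrics for one plan, including
#'   `sum_valve` (see [sum_valve_dose()]).
#' @param age_at_treatment Age in years at treatment.
#' @return Scalar multiplier >= 0.
#' @export
radiation_rate_factor <- function(cfg, endpoint, doses, age_at_treatment) {
  e <- cfg$endpoints[[endpoint]]
  if (is.null(e)) {
    abort(sprintf("endpoint '%s' not in config", endpoint),
          class = "lymphrisk_lookup_error")
  }
  d <- doses[[e$dose_metric]]
  if (is.null(d) || is.na(d)) {
    abort(sprintf("endpoint '%s': dose metric '%s' is missing",
                  endpoint, e$dose_metric),
          class = "lymphrisk_validation_error")
  }
  1 + err_at_age(e, age_at_treatment) * d
}

#' Chemotherapy rate factor for one endpoint
#'
#' Rate ratio applied to the endpoint's background rate for anthracycline
#' exposure; 1 at zero dose and for endpoints with no configured chemotherapy
#' effect (second cancers: the model carries a chemotherapy excess for
#' cardiovascular endpoints only).
#'
#' @inheritParams radiation_rate_factor
#' @param anthracycline_dose Doxorubicin-equivalent dose, mg/m^2.
#' @return Scalar multiplier > 0.
#' @export
chemo_rate_factor <- function(cfg, endpoint, anthracycline_dose) {
  if (anthracycline_dose < 0) {
    abort("anthracycline_dose must be >= 0",
          class = "lymphrisk_validation_error")
  }
  if (anthracycline_dose == 0) return(1)
  bands <- cfg$endpoints[[endpoint]]$chemo_rr %||% list()
  for (b in bands) {
    lo <- as.numeric(b$dose_lo %||% 0)
    hi <- if (is.null(b$dose_hi)) Inf else as.numeric(b$dose_hi)
    if (anthracycline_dose >= lo && anthracycline_dose < hi) {
      return(as.numeric(b$rr))
    }
  }
  1
}

#' Smoking rate factor for one endpoint
#'
#' Never-smokers are the reference (factor 1). Current smokers receive the
#' endpoint's configured rate ratio; former smokers are pooled with current
#' smokers by default, or use `smoking_rr_former` when the config provides
#' one. Unknown status is treated as never-smoking (the conservative
#' default; flagged downstream). Endpoints without a configured ratio get 1.
#'
#' @inheritParams radiation_rate_factor
#' @param smoking_status One of "never", "current", "former", "unknown".
#' @return Scalar multiplier > 0.
#' @export
smoking_rate_factor <- function(cfg, endpoint, smoking_status) {
  if (!smoking_status %in% c("never", "current", "former", "unknown")) {
    abort(sprintf("unknown smoking status '%s'", smoking_status),
          class = "lymphrisk_validation_error")
  }
  if (smoking_status %in% c("never", "unknown")) return(1)
  e <- cfg$endpoints[[endpoint]]
  if (smoking_status == "former" && !is.null(e$smoking_rr_former)) {
    return(as.numeric(e$smoking_rr_former))
  }
  as.numeric(e$smoking_rr %||% 1)
}

#' The dose metric driving each endpoint
#'
#' @param cfg A `lymphrisk_config`.
#' @return A tibble with columns `endpoint` and `dose_metric`.
#' @export
dose_metric_map <- function(cfg) {
  tibble(
    endpoint = names(cfg$endpoints),
    dose_metric = unname(vapply(cfg$endpoints, function(e) e$dose_metric, ""))
  )
}
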