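#' Age bands for standardization strata
#'
#' Cuts ages at treatment into half-open bands of `width` years, with an
#' open-ended top band starting at `top`.
#'
#' @param age Numeric ages.
#' @param width Band width in years (default 10).
#' @param top Start of the open-ended band (default 80).
#' @return Character band labels such as `"[30,40)"`, `"[80,Inf)"`.
#' @export
age_strata <- function(age, width = 10, top = 80) {
  lo <- pmin(floor(age / width) * width, top)
  hi <- ifelse(lo >= top, Inf, lo + width)
  sprintf("[%g,%s)", lo, ifelse(is.finite(hi), sprintf("%g", hi), "Inf"))
}

#' Directly standardize a mean over age/sex strata
#'
#' Computes the directly standardized mean of `value`: stratum-specific
#' means weighted by a fixed standard population's stratum distribution, so
#' subgroup comparisons are independent of subgroup composition.
#'
#' If a stratum carries positive standard weight but has no observations,
#' the result is flagged; by default the standardized value is then `NA`
#' rather than silently renormalized. With `renormalize = TRUE` the weights
#' of the observed strata are rescaled to sum to 1 (still flagged).
#'
#' @param data A tibble holding `value` and the stratum columns.
#' @param value Name of the value column (string).
#' @param standard A tibble with the stratum columns and a `weight` column
#'   (weights are normalized to sum to 1). Typically built with
#'   [standard_population()] from the full cohort.
#' @param strata Character vector of stratum column names
#'   (default `c("age_band", "sex")`).
#' @param renormalize Renormalize over observed strata when some
#'   positive-weight strata are empty (default FALSE).
#' @return A one-row tibble: `standardized_mean`, `crude_mean`, `n`,
#'   `flagged`.
#' @export
standardize <- function(data, value, standard,
                        strata = c("age_band", "sex"),
                        renormalize = FALSE) {
  standard <- standard |>
    mutate(weight = .data$weight / sum(.data$weight))
  by_stratum <- data |>
    group_by(across(all_of(strata))) |>
    summarise(.mean = mean(.data[[value]]), .n = n(), .groups = "drop")
  joined <- standard |>
    left_join(by_stratum, by = strata)
  missing_mass <- sum(joined$weight[is.na(joined$.mean)])
  flagged <- missing_mass > 0
  present <- filter(joined, !is.na(.data$.mean))
  std <- if (!flagged) {
    sum(present$weight * present$.mean)
  } else if (renormalize) {
    sum(present$weight * present$.mean) / sum(present$weight)
  } else {
    NA_real_
  }
  tibble(
    standardized_mean = std,
    crude_mean = mean(data[[value]]),
    n = nrow(data),
    flagged = flagged
  )
}

#' Stratum distribution of a cohort, for use as a standard population
#'
#' @param cohort A cohort tibble (one or two rows per patient; patients are
#'   de-duplicated by `id`).
#' @param age_band_width Width of age-at-treatment bands, years.
#' @return A tibble with `age_band`, `sex`, `weight` summing to 1.
#' @export
standard_population <- function(cohort, age_band_width = 10) {
  cohort |>
    distinct(.data$id, .data$sex, .data$age) |>
    mutate(age_band = age_strata(.data$age, width = age_band_width)) |>
    count(.data$age_band, .data$sex, name = "n") |>
    mutate(weight = .data$n / sum(.data$n)) |>
    select(all_of(c("age_band", "sex", "weight")))
}

# Subgroup rows reported for each disease group, mirroring the standard
# report layout: cardiovascular risks by heart-overlap and LMSCA subgroups,
# lung and breast cancer by axillary involvement, esophageal overall.
report_subgroups <- function() {
  tribble(
    ~disease_group, ~subgroup, ~filter_col, ~filter_val, ~women_only,
    "cvd", "all_patients", NA, NA, FALSE,
    "cvd", "overlap_lt40", "overlap", "lt40", FALSE,
    "cvd", "overlap_ge40", "overlap", "ge40", FALSE,
    "cvd", "above_lmsca", "lmsca", "above_only", FALSE,
    "cvd", "below_lmsca", "lmsca", "below", FALSE,
    "lung_cancer", "all_patients", NA, NA, FALSE,
    "lung_cancer", "no_axilla", "axilla_group", "no", FALSE,
    "lung_cancer", "axilla", "axilla_group", "yes", FALSE,
    "breast_cancer", "all_women", NA, NA, TRUE,
    "breast_cancer", "no_axilla", "axilla_group", "no", TRUE,
    "breast_cancer", "axilla", "axilla_group", "yes", TRUE,
    "esophageal_cancer", "all_patients", NA, NA, FALSE
  )
}

#' Standardized subgroup-by-modality risk report
#'
#' Assembles the report table: for each disease group (cardiovascular
#' disease, lung, breast and esophageal cancer), reporting subgroup, region
#' and modality, the directly age/sex-standardized mean AMR30 in percent
#' with the per-patient min-max range. Subgroup means are standardized to
#' the full cohort's age/sex distribution (weights renormalized over the
#' strata a subgroup actually contains, which is the usual situation for
#' small subgroups).
#'
#' @param cohort A cohort tibble.
#' @param rates A rate table covering one or more regions (column `country`
#'   holds the region name).
#' @param cfg A `lymphrisk_config`.
#' @param regions Regions to report (default: all in `rates`).
#' @param overlap_threshold Heart-overlap classification threshold.
#' @param age_band_width Standardization age-band width, years.
#' @param ... Passed to [decompose_cohort()] (horizon, combination, latency).
#' @return A tibble classed `lymphrisk_report`: `disease_group`, `subgroup`,
#'   `region`, `modality`, `amr30_pct` (standardized), `crude_pct`,
#'   `range_lo_pct`, `range_hi_pct`, `n`, `flagged`. Attributes carry the
#'   standard population, combination mode and config hash.
#' @export
cohort_report <- function(cohort, rates, cfg, regions = NULL,
                          overlap_threshold = 0.40, age_band_width = 10,
                          ...) {
  cohort <- classify_subgroups(validate_cohort(cohort),
                               overlap_threshold = overlap_threshold)
  regions <- regions %||% unique(rates$country)
  standard <- standard_population(cohort, age_band_width)
  labels <- cohort |>
    distinct(.data$id, .data$sex, .data$age, .data$overlap, .data$lmsca,
             .data$axilla_group) |>
    mutate(age_band = age_strata(.data$age, width = age_band_width))

  specs <- report_subgroups()
  out <- purrr::map_dfr(regions, function(reg) {
    decomp <- decompose_cohort(cohort, filter(rates, .data$country == reg),
                               cfg, ...)
    grouped <- group_decomposition(decomp) |>
      left_join(labels, by = "id") |>
      tidyr::pivot_longer(
        cols = all_of(c("amr30_full_photon", "amr30_full_proton")),
        names_to = "modality", names_prefix = "amr30_full_",
        values_to = "amr30"
      )
    purrr::pmap_dfr(specs, function(disease_group, subgroup, filter_col,
                                    filter_val, women_only) {
      d <- filter(grouped, .data$disease_group == .env$disease_group)
      if (women_only) d <- filter(d, .data$sex == "female")
      if (!is.na(filter_col)) d <- d[d[[filter_col]] == filter_val, ]
      rows <- if (nrow(d) == 0) {
        # empty subgroup: keep the row shape, flagged, nothing standardized
        tibble(modality = c("photon", "proton"), amr30_pct = NA_real_,
               crude_pct = NA_real_, range_lo_pct = NA_real_,
               range_hi_pct = NA_real_, n = 0L, flagged = TRUE)
      } else {
        d |>
          group_by(.data$modality) |>
          group_modify(function(g, key) {
            std <- standardize(g, "amr30", standard, renormalize = TRUE)
            tibble(
              amr30_pct = 100 * std$standardized_mean,
              crude_pct = 100 * std$crude_mean,
              range_lo_pct = 100 * min(g$amr30),
              range_hi_pct = 100 * max(g$amr30),
              n = std$n, flagged = std$flagged
            )
          }) |>
          ungroup()
      }
      rows |>
        mutate(disease_group = disease_group, subgroup = subgroup,
               region = reg)
    })
  }) |>
    select(all_of(c("disease_group", "subgroup", "region", "modality",
                    "amr30_pct", "crude_pct", "range_lo_pct", "range_hi_pct",
                    "n", "flagged")))
  structure(out,
    class = c("lymphrisk_report", class(out)),
    standard = standard,
    config_hash = rlang::hash(unclass(cfg)),
    dots = list(...)
  )
}
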