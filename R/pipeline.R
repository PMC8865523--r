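#' Run the full risk-prediction pipeline from files
#'
#' Reads a cohort CSV, a rates CSV and a dose-response JSON config, runs the
#' decomposition for every requested region, and writes
#' `decomposition.csv` (patient x endpoint, full precision), `report.csv`
#' (disease x subgroup x region x modality, standardized percentages to one
#' decimal) and `metadata.json` (all modelling decisions in force) into
#' `out_dir`.
#'
#' @param cohort_path,rates_path,config_path Input file paths.
#' @param out_dir Output directory (created if needed).
#' @param regions Regions to report; default all in the rates file.
#' @param horizon Projection horizon, years.
#' @param combination `"multiplicative"` or `"additive_err"`.
#' @param overlap_threshold Heart-overlap classification threshold.
#' @param latency Years before treatment excesses apply.
#' @return Invisibly, a list with the decomposition, report and metadata.
#' @export
run_predict <- function(cohort_path, rates_path, config_path, out_dir,
                        regions = NULL, horizon = 30,
                        combination = "multiplicative",
                        overlap_threshold = 0.40, latency = 0) {
  for (p in c(cohort_path, rates_path, config_path)) {
    if (!file.exists(p)) {
      abort(sprintf("input file not found: %s", p),
            class = "lymphrisk_io_error")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_cohort(cohort_path)
  rates <- read_rate_table(rates_path)
  cfg <- load_config(config_path)
  regions <- regions %||% unique(rates$country)

  decomp <- purrr::map_dfr(regions, function(reg) {
    decompose_cohort(cohort, filter(rates, .data$country == reg), cfg,
                     horizon = horizon, combination = combination,
                     latency = latency) |>
      mutate(region = reg)
  })
  report <- cohort_report(cohort, rates, cfg, regions = regions,
                          overlap_threshold = overlap_threshold,
                          horizon = horizon, combination = combination,
                          latency = latency)
  metadata <- list(
    horizon = horizon, combination = combination,
    overlap_threshold = overlap_threshold, latency = latency,
    regions = regions,
    smoking_handling = "former pooled with current unless config overrides; unknown treated as never and flagged",
    standard_population = "full input cohort age/sex distribution, 10-year bands",
    subgroup_weights = "renormalized over observed strata",
    config_hash = rlang::hash(unclass(cfg)),
    n_patients = length(unique(cohort$id))
  )
  readr::write_csv(decomp, file.path(out_dir, "decomposition.csv"))
  report_out <- report |>
    mutate(across(c("amr30_pct", "crude_pct", "range_lo_pct",
                    "range_hi_pct"), ~ round(.x, 1)))
  readr::write_csv(report_out, file.path(out_dir, "report.csv"))
  jsonlite::write_json(metadata, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(decomposition = decomp, report = report,
                 metadata = metadata))
}

#' Run the dose-comparison analysis from files
#'
#' @inheritParams run_predict
#' @param subgroup Optional subgroup filter: a named value such as
#'   `c(overlap = "ge40")` restricting the table to matching patients.
#' @return Invisibly, the comparison tibble (also written to
#'   `dose_table.csv` in `out_dir`).
#' @export
run_compare_doses <- function(cohort_path, out_dir,
                              overlap_threshold = 0.40, subgroup = NULL) {
  if (!file.exists(cohort_path)) {
    abort(sprintf("input file not found: %s", cohort_path),
          class = "lymphrisk_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_cohort(cohort_path)
  if (!is.null(subgroup)) {
    labelled <- classify_subgroups(cohort, overlap_threshold)
    keep <- labelled[[names(subgroup)]] == unname(subgroup)
    cohort <- cohort[keep, ]
  }
  tbl <- compare_doses(cohort, overlap_threshold = overlap_threshold)
  readr::write_csv(tbl, file.path(out_dir, "dose_table.csv"))
  invisible(tbl)
}

#' Compute subgroup-average dose presets from a cohort
#'
#' Presets used in what-if scenarios: average doses over a subgroup and
#' modality, e.g. `"ge40_overlap_means"` (cardiac doses among patients with
#' >=40% CTV-to-heart overlap, lung dose among patients with axillary
#' involvement, as used for smoking scenario panels).
#'
#' @param cohort A cohort tibble.
#' @param preset `"ge40_overlap_means"` or `"lt40_overlap_means"`.
#' @param overlap_threshold Heart-overlap threshold.
#' @return A list with `photon` and `proton` named dose vectors.
#' @export
dose_preset <- function(cohort, preset = "ge40_overlap_means",
                        overlap_threshold = 0.40) {
  presets <- c("ge40_overlap_means", "lt40_overlap_means")
  if (!preset %in% presets) {
    abort(sprintf("unknown preset '%s'; available: %s", preset,
                  paste(presets, collapse = ", ")),
          class = "lymphrisk_validation_error")
  }
  lab <- classify_subgroups(validate_cohort(cohort), overlap_threshold)
  ov <- if (preset == "ge40_overlap_means") "ge40" else "lt40"
  cardiac <- c("whole_heart", "left_ventricle", "aortic_valve",
               "mitral_valve", "tricuspid_valve")
  mean_doses <- function(mod) {
    heart <- lab |>
      filter(.data$overlap == ov, .data$modality == .env$mod) |>
      summarise(across(all_of(cardiac), mean))
    lung <- lab |>
      filter(.data$axilla_group == "yes", .data$modality == .env$mod) |>
      summarise(lungs = mean(.data$lungs))
    c(unlist(heart), unlist(lung))
  }
  list(photon = mean_doses("photon"), proton = mean_doses("proton"))
}

#' Run a smoking/exposure scenario
#'
#' Projects AMR30 decompositions for one hypothetical individual, writes a
#' scenario table, and (optionally) a stacked-bar decomposition figure.
#'
#' @inheritParams scenario_risk
#' @param out_dir Output directory; `scenario.csv` (and `scenario.png` if
#'   `plot = TRUE`) are written there.
#' @param plot Also write a stacked decomposition figure.
#' @param ... Passed to [scenario_risk()].
#' @return Invisibly, the scenario decomposition.
#' @export
run_scenario <- function(age, sex, smoking, doses_photon, doses_proton,
                         anthracycline, rates, cfg, out_dir, plot = FALSE,
                         ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  decomp <- scenario_risk(age, sex, smoking, doses_photon, doses_proton,
                          anthracycline, rates, cfg, ...)
  readr::write_csv(decomp, file.path(out_dir, "scenario.csv"))
  if (plot) {
    p <- autoplot(decomp)
    ggplot2::ggsave(file.path(out_dir, "scenario.png"), p,
                    width = 7, height = 4.5, dpi = 150)
  }
  invisible(decomp)
}
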