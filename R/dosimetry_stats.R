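#' Paired photon-vs-proton dose difference test
#'
#' One-sample t test of the per-patient dose differences for one organ
#' metric against zero. The difference is taken as `proton - photon` by
#' default, so negative means proton plans spare the organ.
#'
#' @param cohort A cohort tibble (both modality rows per patient).
#' @param metric Dose metric column name, or `"sum_valve"` for the weighted
#'   valve summary.
#' @param order `"proton_minus_photon"` (default) or `"photon_minus_proton"`.
#' @return A `lymphrisk_paired_test` object with `metric`, `n`,
#'   `mean_difference`, `range_lo`, `range_hi`, `p_value` and the
#'   per-patient `differences`. [tidy()] and [glance()] methods are
#'   provided.
#' @export
paired_difference_test <- function(cohort, metric,
                                   order = c("proton_minus_photon",
                                             "photon_minus_proton")) {
  order <- match.arg(order)
  d <- dose_differences(cohort, metric, order)
  if (length(d$diff) < 2) {
    abort("need at least 2 patients with both modalities",
          class = "lymphrisk_validation_error")
  }
  m <- mean(d$diff)
  if (stats::sd(d$diff) == 0) {
    p <- if (m == 0) 1 else 1e-15  # zero variance: degenerate t; sentinel p
  } else {
    p <- t.test(d$diff, mu = 0)$p.value
  }
  structure(
    list(metric = metric, order = order, n = length(d$diff),
         mean_difference = m, range_lo = min(d$diff), range_hi = max(d$diff),
         p_value = p, differences = setNames(d$diff, d$id)),
    class = "lymphrisk_paired_test"
  )
}

# Per-patient modality dose differences for one metric.
dose_differences <- function(cohort, metric, order = "proton_minus_photon") {
  cohort <- validate_cohort(cohort)
  wide <- cohort |>
    mutate(sum_valve = sum_valve_dose(.data$aortic_valve, .data$mitral_valve,
                                      .data$tricuspid_valve)) |>
    select(all_of(c("id", "modality", metric))) |>
    tidyr::pivot_wider(names_from = "modality", values_from = all_of(metric))
  if (!all(c("photon", "proton") %in% names(wide))) {
    abort("cohort must contain both photon and proton rows",
          class = "lymphrisk_validation_error")
  }
  wide <- filter(wide, !is.na(.data$photon) & !is.na(.data$proton))
  diff <- if (order == "proton_minus_photon") {
    wide$proton - wide$photon
  } else {
    wide$photon - wide$proton
  }
  list(id = wide$id, diff = diff)
}

#' @export
print.lymphrisk_paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired dose difference (%s), %s: n = %d, mean = %.3f Gy (range %.3f to %.3f), p = %.3g\n",
    gsub("_", " ", x$order), x$metric, x$n, x$mean_difference,
    x$range_lo, x$range_hi, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.lymphrisk_paired_test <- function(x, ...) {
  tibble(
    metric = x$metric, estimate = x$mean_difference,
    range_lo = x$range_lo, range_hi = x$range_hi,
    p.value = x$p_value, n = x$n
  )
}

#' @export
glance.lymphrisk_paired_test <- function(x, ...) {
  tibble(n = x$n, p.value = x$p_value)
}

#' Between-subgroup test of modality dose differences
#'
#' Regresses the per-patient modality difference for one metric on a
#' two-level subgroup indicator (ordinary least squares with homoskedastic
#' errors, equivalent to the pooled-variance two-sample t test) and reports
#' the indicator's two-sided t-distribution p-value. Welch inference is
#' available by flag.
#'
#' @inheritParams paired_difference_test
#' @param grouping Name of a subgroup column (e.g. from
#'   [classify_subgroups()]) or a vector with one label per patient.
#' @param welch Use Welch (unequal-variance) inference instead of OLS.
#' @return A `lymphrisk_subgroup_test` with `estimate` (difference in mean
#'   modality differences between the two levels), `p_value`, group labels
#'   and sizes.
#' @export
subgroup_difference_test <- function(cohort, metric, grouping,
                                     order = c("proton_minus_photon",
                                               "photon_minus_proton"),
                                     welch = FALSE) {
  order <- match.arg(order)
  d <- dose_differences(cohort, metric, order)
  if (is.character(grouping) && length(grouping) == 1) {
    labels <- classify_subgroups(validate_cohort(cohort)) |>
      distinct(.data$id, g = .data[[grouping]])
    g <- labels$g[match(d$id, labels$id)]
  } else {
    g <- rep_len(grouping, length(d$id))
  }
  lv <- sort(unique(g))
  if (length(lv) != 2) {
    abort("grouping must have exactly two non-empty levels",
          class = "lymphrisk_validation_error")
  }
  if (welch) {
    tt <- t.test(d$diff[g == lv[2]], d$diff[g == lv[1]], var.equal = FALSE)
    est <- mean(d$diff[g == lv[2]]) - mean(d$diff[g == lv[1]])
    p <- tt$p.value
  } else {
    fit <- lm(d$diff ~ factor(g, levels = lv))
    est <- unname(coef(fit)[2])
    p <- summary(fit)$coefficients[2, 4]
  }
  structure(
    list(metric = metric, grouping_levels = lv, estimate = est,
         p_value = p, n = as.vector(table(factor(g, levels = lv))),
         welch = welch),
    class = "lymphrisk_subgroup_test"
  )
}

#' @export
print.lymphrisk_subgroup_test <- function(x, ...) {
  cat(sprintf(
    "Subgroup difference (%s vs %s), %s: estimate = %.3f Gy, p = %.3g (n = %d/%d)\n",
    x$grouping_levels[2], x$grouping_levels[1], x$metric, x$estimate,
    x$p_value, x$n[1], x$n[2]
  ))
  invisible(x)
}

#' @export
tidy.lymphrisk_subgroup_test <- function(x, ...) {
  tibble(
    metric = x$metric,
    contrast = paste(x$grouping_levels[2], "-", x$grouping_levels[1]),
    estimate = x$estimate, p.value = x$p_value
  )
}

#' @export
glance.lymphrisk_subgroup_test <- function(x, ...) {
  tibble(n = sum(x$n), p.value = x$p_value)
}

#' Dose comparison table across metrics and subgroups
#'
#' Builds the full dosimetric comparison: per organ metric and patient
#' group (all patients plus the overlap, LMSCA and axilla subgroups where
#' relevant), the average photon and proton doses with ranges, the paired
#' mean difference and its p-value, and the between-subgroup p-value.
#'
#' @param cohort A cohort tibble.
#' @param metrics Dose metrics to report (default: all, with `sum_valve`
#'   replacing the individual valve doses).
#' @param overlap_threshold Heart-overlap classification threshold.
#' @return A tibble with one row per (metric, patient group).
#' @export
compare_doses <- function(cohort,
                          metrics = c("whole_heart", "left_ventricle",
                                      "sum_valve", "carotid_arteries",
                                      "lungs", "breast", "esophagus",
                                      "normal_tissue"),
                          overlap_threshold = 0.40) {
  cohort <- classify_subgroups(validate_cohort(cohort),
                               overlap_threshold = overlap_threshold)
  groupings <- list(
    whole_heart = c("overlap", "lmsca"),
    left_ventricle = c("overlap", "lmsca"),
    sum_valve = c("overlap", "lmsca"),
    lungs = "axilla_group",
    breast = "axilla_group"
  )
  one_row <- function(d, metric, group_label) {
    sub <- filter(d, .data$modality %in% c("photon", "proton"))
    ph <- sub[[metric]][sub$modality == "photon"]
    pr <- sub[[metric]][sub$modality == "proton"]
    diffs <- dose_differences(sub, metric)$diff
    # singleton subgroups get summary rows without inferential statistics
    p <- if (length(diffs) >= 2) {
      paired_difference_test(sub, metric)$p_value
    } else {
      NA_real_
    }
    tibble(
      metric = metric, patient_group = group_label,
      n = length(diffs),
      photon_mean = mean(ph, na.rm = TRUE),
      photon_lo = min(ph, na.rm = TRUE), photon_hi = max(ph, na.rm = TRUE),
      proton_mean = mean(pr, na.rm = TRUE),
      proton_lo = min(pr, na.rm = TRUE), proton_hi = max(pr, na.rm = TRUE),
      mean_difference = mean(diffs),
      diff_lo = min(diffs), diff_hi = max(diffs),
      p_paired = p
    )
  }
  dat <- cohort |>
    mutate(sum_valve = sum_valve_dose(.data$aortic_valve, .data$mitral_valve,
                                      .data$tricuspid_valve))
  purrr::map_dfr(metrics, function(m) {
    d <- dat
    if (m == "breast") d <- filter(d, .data$sex == "female", !is.na(.data$breast))
    rows <- one_row(d, m, "all")
    for (gcol in groupings[[m]] %||% character()) {
      lv <- sort(unique(d[[gcol]]))
      p_between <- if (length(lv) == 2) {
        tryCatch(subgroup_difference_test(d, m, gcol)$p_value,
                 error = function(e) NA_real_)
      } else {
        NA_real_
      }
      for (v in lv) {
        r <- one_row(d[d[[gcol]] == v, ], m, paste(gcol, v, sep = "_"))
        r$p_between <- p_between
        rows <- bind_rows(rows, r)
      }
    }
    if (!"p_between" %in% names(rows)) rows$p_between <- NA_real_
    rows
  })
}
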