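#' @export
print.lymphrisk_decomposition <- function(x, ...) {
  if (!all(c("id", "endpoint") %in% names(x))) {
    return(NextMethod())
  }
  cat(sprintf(
    "AMR%d decomposition: %d patients x %d endpoints (%s combination%s)\n",
    attr(x, "horizon") %||% 30, length(unique(x$id)),
    length(unique(x$endpoint)),
    attr(x, "combination") %||% "multiplicative",
    if (!is.null(attr(x, "region"))) {
      sprintf(", region %s", paste(attr(x, "region"), collapse = "/"))
    } else ""
  ))
  NextMethod()
}

#' Tidy a risk decomposition into long layer format
#'
#' One row per (patient, endpoint, modality, component), where component is
#' the additive layer (`background`, `excess_chemo`, `excess_rt`) whose sum
#' is the full-model AMR30 for that modality.
#'
#' @param x A `lymphrisk_decomposition`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `endpoint`, `modality`, `component`,
#'   `amr30`.
#' @export
tidy.lymphrisk_decomposition <- function(x, ...) {
  purrr::map_dfr(c("photon", "proton"), function(m) {
    tibble(
      id = rep(x$id, 3),
      endpoint = rep(x$endpoint, 3),
      modality = m,
      component = rep(c("background", "excess_chemo", "excess_rt"),
                      each = nrow(x)),
      amr30 = c(x$amr30_background, x$excess_chemo,
                x[[paste0("excess_rt_", m)]])
    )
  })
}

#' @export
glance.lymphrisk_decomposition <- function(x, ...) {
  tibble(
    n_patients = length(unique(x$id)),
    n_endpoints = length(unique(x$endpoint)),
    horizon = attr(x, "horizon") %||% 30,
    combination = attr(x, "combination") %||% "multiplicative",
    mean_amr30_full_photon = mean(x$amr30_full_photon),
    mean_amr30_full_proton = mean(x$amr30_full_proton)
  )
}

#' Stacked decomposition plot
#'
#' Figure-style stacked bars: per modality (and per endpoint or disease
#' group), the background, chemotherapy-excess and radiation-excess layers
#' of the cohort-mean AMR30.
#'
#' @param object A `lymphrisk_decomposition`.
#' @param by_group Collapse endpoints to disease groups first (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lymphrisk_decomposition <- function(object, by_group = TRUE, ...) {
  d <- if (by_group) {
    grouped <- group_decomposition(object)
    purrr::map_dfr(c("photon", "proton"), function(m) {
      tibble(
        unit = rep(grouped$disease_group, 3),
        modality = m,
        component = rep(c("background", "excess_chemo", "excess_rt"),
                        each = nrow(grouped)),
        amr30 = c(grouped$amr30_background, grouped$excess_chemo,
                  grouped[[paste0("excess_rt_", m)]]),
        id = rep(grouped$id, 3)
      )
    }) |>
      group_by(.data$unit, .data$modality, .data$component) |>
      summarise(amr30 = mean(.data$amr30), .groups = "drop")
  } else {
    tidy(object) |>
      group_by(unit = .data$endpoint, .data$modality, .data$component) |>
      summarise(amr30 = mean(.data$amr30), .groups = "drop")
  }
  d |>
    mutate(component = factor(.data$component,
                              c("excess_rt", "excess_chemo", "background"))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$modality,
                                 y = 100 * .data$amr30,
                                 fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~unit, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "30-year absolute mortality risk (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dose-comparison plot
#'
#' Paired photon/proton mean doses per metric with the paired difference
#' annotated.
#'
#' @param comparison Output of [compare_doses()].
#' @param group Patient group to display (default `"all"`).
#' @return A ggplot object.
#' @export
plot_dose_comparison <- function(comparison, group = "all") {
  comparison |>
    filter(.data$patient_group == group) |>
    tidyr::pivot_longer(all_of(c("photon_mean", "proton_mean")),
                        names_to = "modality", values_to = "mean_dose") |>
    mutate(modality = sub("_mean$", "", .data$modality)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$metric, y = .data$mean_dose,
                                 fill = .data$modality)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean dose (Gy)", fill = NULL) +
    ggplot2::theme_minimal()
}
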