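#' Read a background mortality rate table
#'
#' Reads a CSV of cause-, sex- and age-specific mortality rates in the layout
#' of national statistics extracts: one row per (country, sex, cause, age
#' band), rates expressed per 100,000 person-years. Age bands are half-open
#' `[age_lo, age_hi)`; the last band of each (country, sex, cause) series is
#' open-ended and carries an empty/NA `age_hi`.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping the canonical column
#'   names (`country`, `sex`, `cause`, `age_lo`, `age_hi`, `rate_per_100k`)
#'   to the names actually used in the file.
#' @return A validated rate table: a tibble with columns `country`, `sex`,
#'   `cause`, `age_lo`, `age_hi` (NA for the open-ended band) and
#'   `rate_per_100k`, classed `lymphrisk_rates`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(
#'   country = "X", sex = "female", cause = "stroke",
#'   age_lo = c(0, 50), age_hi = c(50, NA), rate_per_100k = c(1, 120)
#' ), path)
#' read_rate_table(path)
#' @export
read_rate_table <- function(path, schema = NULL) {
  canonical <- c("country", "sex", "cause", "age_lo", "age_hi", "rate_per_100k")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    missing_map <- setdiff(canonical, names(schema))
    schema <- c(schema, setNames(missing_map, missing_map))
    for (col in canonical) {
      src <- unname(schema[[col]])
      if (!src %in% names(raw)) {
        abort(sprintf("rate table is missing required column '%s'", src),
              class = "lymphrisk_schema_error")
      }
    }
    raw <- rename(raw, !!!setNames(unname(schema[canonical]), canonical))
  }
  missing_cols <- setdiff(canonical, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("rate table is missing required column '%s'",
                  missing_cols[[1]]),
          class = "lymphrisk_schema_error")
  }
  tbl <- raw |>
    select(all_of(canonical)) |>
    mutate(
      age_lo = as.numeric(.data$age_lo),
      age_hi = as.numeric(.data$age_hi),
      rate_per_100k = as.numeric(.data$rate_per_100k)
    ) |>
    as_tibble()
  validate_rate_table(tbl)
}

#' Validate a rate table
#'
#' Checks that, within every (country, sex, cause) series, the age bands
#' partition `[0, Inf)` with no gaps or overlaps, that exactly one band is
#' open-ended, and that all rates are non-negative.
#'
#' @param tbl A tibble with the rate-table columns (see [read_rate_table()]).
#' @return The table, invisibly classed `lymphrisk_rates`.
#' @export
validate_rate_table <- function(tbl) {
  if (any(is.na(tbl$rate_per_100k)) || any(tbl$rate_per_100k < 0)) {
    bad <- tbl[is.na(tbl$rate_per_100k) | tbl$rate_per_100k < 0, ][1, ]
    abort(sprintf(
      "negative or missing rate for (%s, %s, %s) band starting at %s",
      bad$country, bad$sex, bad$cause, bad$age_lo
    ), class = "lymphrisk_validation_error")
  }
  check_series <- function(d) {
    d <- arrange(d, .data$age_lo)
    key <- sprintf("(%s, %s, %s)", d$country[1], d$sex[1], d$cause[1])
    if (d$age_lo[1] != 0) {
      abort(sprintf("%s: bands do not start at age 0 (first band starts at %s)",
                    key, d$age_lo[1]),
            class = "lymphrisk_validation_error")
    }
    n_open <- sum(is.na(d$age_hi))
    if (n_open == 0) {
      abort(sprintf("%s: no open-ended final band (age_hi must be empty)", key),
            class = "lymphrisk_validation_error")
    }
    if (n_open > 1 || !is.na(d$age_hi[nrow(d)]) && nrow(d) > 1) {
      abort(sprintf("%s: open-ended band must be last and unique", key),
            class = "lymphrisk_validation_error")
    }
    if (nrow(d) > 1) {
      hi <- d$age_hi[-nrow(d)]
      lo_next <- d$age_lo[-1]
      bad <- which(hi != lo_next)
      if (length(bad) > 0) {
        i <- bad[1]
        what <- if (hi[i] < lo_next[i]) "gap" else "overlap"
        abort(sprintf("%s: %s between bands [%s,%s) and [%s,...)",
                      key, what, d$age_lo[i], hi[i], lo_next[i]),
              class = "lymphrisk_validation_error")
      }
      if (any(hi <= d$age_lo[-nrow(d)])) {
        abort(sprintf("%s: band with non-positive width", key),
              class = "lymphrisk_validation_error")
      }
    }
    invisible(NULL)
  }
  tbl |>
    group_by(.data$country, .data$sex, .data$cause) |>
    group_walk(~ check_series(mutate(.x,
      country = .y$country, sex = .y$sex, cause = .y$cause
    )))
  class(tbl) <- unique(c("lymphrisk_rates", class(tbl)))
  tbl
}

#' Annual background hazard at an attained age
#'
#' Looks up the mortality rate of the age band containing `attained_age` and
#' converts it from deaths per 100,000 person-years to an annual hazard per
#' person-year. Rates are piecewise-constant within bands; bands are
#' half-open `[lo, hi)`; ages beyond the last closed band use the open-ended
#' band.
#'
#' @param rates A rate table (see [read_rate_table()]), restricted to one
#'   country/region or carrying a `country` column with a single value.
#' @param sex `"male"` or `"female"` (recycled against `attained_age`).
#' @param cause Endpoint identifier (recycled).
#' @param attained_age Integer (or numeric) ages, >= 0. Vectorized.
#' @return Numeric vector of annual hazards (per person-year).
#' @examples
#' tbl <- tibble::tibble(
#'   country = "X", sex = "male", cause = "stroke",
#'   age_lo = c(0, 30, 35), age_hi = c(30, 35, NA),
#'   rate_per_100k = c(10, 200, 400)
#' )
#' hazard(tbl, "male", "stroke", 32) # 200 / 1e5 = 0.002
#' @export
hazard <- function(rates, sex, cause, attained_age) {
  if (any(attained_age < 0)) {
    abort("attained_age must be >= 0", class = "lymphrisk_validation_error")
  }
  n <- max(length(sex), length(cause), length(attained_age))
  sex <- rep_len(sex, n)
  cause <- rep_len(cause, n)
  attained_age <- rep_len(attained_age, n)
  out <- numeric(n)
  for (key in unique(paste(sex, cause, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    idx <- sex == parts[1] & cause == parts[2]
    series <- rates[rates$sex == parts[1] & rates$cause == parts[2], ]
    if (nrow(series) == 0) {
      abort(sprintf("no rates for sex '%s', cause '%s'", parts[1], parts[2]),
            class = "lymphrisk_lookup_error")
    }
    series <- arrange(series, .data$age_lo)
    band <- findInterval(attained_age[idx], series$age_lo)
    out[idx] <- series$rate_per_100k[band] / 1e5
  }
  out
}

#' Aggregate country rate tables into a region table
#'
#' Builds a single region-level rate table as a (optionally weighted) mean of
#' member-country rates. Countries whose band structures disagree are first
#' expanded to 1-year resolution by piecewise-constant fill, which is
#' lossless under the piecewise-constant rate model, then aggregated and the
#' common band structure of the first country is used for output when band
#' structures agree; otherwise 1-year bands are returned.
#'
#' @param rates A rate table holding all member countries (column `country`).
#' @param region_name Name for the output region.
#' @param member_countries Character vector of country identifiers.
#' @param weights Optional non-negative weights aligned with
#'   `member_countries`; they are normalized to sum to 1. Equal weights when
#'   absent.
#' @return A rate table with `country` set to `region_name`.
#' @export
build_region_table <- function(rates, region_name, member_countries,
                               weights = NULL) {
  missing_c <- setdiff(member_countries, unique(rates$country))
  if (length(missing_c) > 0) {
    abort(sprintf("country '%s' not present in rate inputs", missing_c[[1]]),
          class = "lymphrisk_lookup_error")
  }
  if (is.null(weights)) {
    weights <- rep(1, length(member_countries))
  }
  if (length(weights) != length(member_countries) || any(weights < 0)) {
    abort("weights must be non-negative and align 1:1 with member_countries",
          class = "lymphrisk_validation_error")
  }
  weights <- weights / sum(weights)
  wtbl <- tibble(country = member_countries, .w = weights)

  members <- filter(rates, .data$country %in% member_countries)
  # same band structure across countries?
  sig <- members |>
    group_by(.data$country) |>
    summarise(sig = paste(sort(paste(.data$sex, .data$cause, .data$age_lo,
                                     .data$age_hi)), collapse = ";"),
              .groups = "drop")
  same_bands <- length(unique(sig$sig)) == 1

  if (!same_bands) {
    members <- expand_to_unit_bands(members)
  }
  out <- members |>
    inner_join(wtbl, by = "country") |>
    group_by(.data$sex, .data$cause, .data$age_lo, .data$age_hi) |>
    summarise(rate_per_100k = sum(.data$rate_per_100k * .data$.w) / sum(.data$.w),
              .groups = "drop") |>
    mutate(country = region_name) |>
    select(all_of(c("country", "sex", "cause", "age_lo", "age_hi",
                    "rate_per_100k")))
  validate_rate_table(out)
}

# Expand a rate table to 1-year bands up to the max closed boundary, keeping
# one open-ended band. Piecewise-constant fill: each year inherits its band's
# rate, so no information is lost or invented.
expand_to_unit_bands <- function(tbl) {
  top <- max(tbl$age_lo[is.na(tbl$age_hi)])
  tbl |>
    group_by(.data$country, .data$sex, .data$cause) |>
    group_modify(function(d, key) {
      d <- arrange(d, .data$age_lo)
      ages <- seq(0, top - 1)
      band <- findInterval(ages, d$age_lo)
      tibble(
        age_lo = c(ages, top),
        age_hi = c(ages + 1, NA),
        rate_per_100k = c(d$rate_per_100k[band],
                          d$rate_per_100k[nrow(d)])
      )
    }) |>
    ungroup()
}
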