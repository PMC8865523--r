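test_that("cohort simulation is deterministic and matches its own labels", {
  spec <- cohort_sim_spec(n_patients = 30, seed = 42)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # drawn subgroup labels are reproduced exactly by the classifier
  truth <- attr(a, "truth")
  lab <- classify_subgroups(a) |> distinct(id, overlap, lmsca, axilla_group)
  expect_equal(sum(lab$overlap == "ge40"), truth$n_ge40)
  expect_equal(sum(lab$lmsca == "below"), truth$n_below_lmsca)
  expect_equal(sum(lab$axilla_group == "yes"), truth$n_axilla)

  # default study-size proportions land near their targets
  big <- simulate_cohort(cohort_sim_spec(n_patients = 80, seed = 7))
  tb <- attr(big, "truth")
  expect_gt(tb$n_ge40, stats::qbinom(0.005, 80, 0.29))
  expect_lt(tb$n_ge40, stats::qbinom(0.995, 80, 0.29))
  ages <- distinct(big, id, age)$age
  expect_true(all(ages >= 18 & ages <= 79))
  expect_gt(median(ages), 24)
  expect_lt(median(ages), 38)

  # paired schema: two rows per patient, non-negative doses
  expect_equal(nrow(big), 160)
  expect_true(all(count(big, id)$n == 2))
  doses <- select(big, whole_heart:normal_tissue)
  expect_true(all(as.matrix(doses) >= 0, na.rm = TRUE))
})

test_that("dose generation respects the qualitative modality pattern", {
  cohort <- simulate_cohort(cohort_sim_spec(n_patients = 80, seed = 12))
  wide <- function(metric) {
    ph <- cohort[[metric]][cohort$modality == "photon"]
    pr <- cohort[[metric]][cohort$modality == "proton"]
    mean(pr, na.rm = TRUE) - mean(ph, na.rm = TRUE)
  }
  for (m in c("left_ventricle", "lungs", "breast", "normal_tissue")) {
    expect_lt(wide(m), 0)
  }
  expect_gt(wide("carotid_arteries"), 0)

  # zero dose scale zeroes every dose
  z <- simulate_cohort(cohort_sim_spec(n_patients = 10, seed = 1,
                                       dose_scale = 0))
  expect_true(all(as.matrix(select(z, whole_heart:normal_tissue)) == 0,
                  na.rm = TRUE))

  expect_error(cohort_sim_spec(p_ge40 = 1.4),
               class = "lymphrisk_validation_error")
})

test_that("synthetic rate tables follow Gompertz structure and scaling", {
  rates <- simulate_rate_tables()
  expect_s3_class(rates, "lymphrisk_rates")
  expect_setequal(unique(rates$country),
                  c("united_states", "western_europe", "eastern_europe",
                    "japan"))
  expect_setequal(unique(rates$cause), c(ALL_ENDPOINTS, "all_other_causes"))

  # rates increase with age within every series
  inc <- rates |>
    group_by(country, sex, cause) |>
    arrange(age_lo, .by_group = TRUE) |>
    summarise(ok = all(diff(rate_per_100k) > 0), .groups = "drop")
  expect_true(all(inc$ok))

  # constant-hazard spec gives identical rates in every band
  const <- simulate_rate_tables(rate_sim_spec(
    causes = mutate(lymphrisk:::default_gompertz_params(), slope = 0)
  ))
  flat <- const |>
    group_by(country, sex, cause) |>
    summarise(k = dplyr::n_distinct(rate_per_100k), .groups = "drop")
  expect_true(all(flat$k == 1))

  # doubling the baseline doubles every band
  doubled <- simulate_rate_tables(rate_sim_spec(
    causes = mutate(lymphrisk:::default_gompertz_params(),
                    baseline = 2 * baseline)
  ))
  expect_equal(doubled$rate_per_100k, 2 * rates$rate_per_100k)

  expect_error(rate_sim_spec(causes = mutate(
    lymphrisk:::default_gompertz_params(), slope = -0.1
  )), class = "lymphrisk_validation_error")
})

test_that("regional scaling orders background cardiovascular risk as intended", {
  rates <- simulate_rate_tables()
  cfg <- toy_config()
  cohort <- simulate_cohort(cohort_sim_spec(n_patients = 25, seed = 31))
  bg_cvd <- vapply(
    c("eastern_europe", "united_states", "western_europe", "japan"),
    function(r) {
      d <- decompose_cohort(cohort, filter(rates, country == r), cfg)
      g <- group_decomposition(d)
      mean(g$amr30_background[g$disease_group == "cvd"])
    }, 0
  )
  expect_true(all(diff(bg_cvd) < 0))
})

test_that("the fixture bundle is complete, loadable and idempotent", {
  dir1 <- withr::local_tempdir()
  paths <- make_fixture_bundle(dir1)
  expect_true(all(file.exists(paths)))

  cohort <- read_cohort(file.path(dir1, "cohort.csv"))
  rates <- read_rate_table(file.path(dir1, "rates.csv"))
  cfg <- load_config(file.path(dir1, "dose_response.json"))
  expect_equal(length(unique(cohort$id)), 12)
  expect_setequal(unique(rates$country), c("united_states", "japan"))

  # end-to-end smoke: decomposition runs quickly on the bundle
  t0 <- Sys.time()
  d <- decompose_cohort(cohort, filter(rates, country == "united_states"),
                        cfg)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  expect_equal(nrow(d), 12 * 8)

  # regeneration is byte-identical
  dir2 <- withr::local_tempdir()
  make_fixture_bundle(dir2)
  for (f in c("cohort.csv", "rates.csv", "dose_response.json", "truth.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
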