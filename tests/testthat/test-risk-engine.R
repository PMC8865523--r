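test_that("cumulative mortality matches constant-hazard closed forms", {
  haz <- matrix(0.01, nrow = 30, ncol = 2,
                dimnames = list(NULL, c("a", "other")))
  sched <- schedule_from_matrix(haz)
  expect_equal(cumulative_mortality(sched, cause = "a"),
               0.5 * (1 - exp(-0.6)), tolerance = 1e-14)

  solo <- schedule_from_matrix(matrix(0.02, 30, 1,
                                      dimnames = list(NULL, "a")))
  expect_equal(cumulative_mortality(solo, cause = "a"), 1 - exp(-0.6),
               tolerance = 1e-14)

  # overwhelming competing hazard suppresses the cause of interest
  crush <- schedule_from_matrix(cbind(a = rep(0.01, 30),
                                      other = rep(1e6, 30)))
  expect_lt(cumulative_mortality(crush, cause = "a"), 1e-7)

  # zero-hazard years contribute nothing and cause no 0/0
  gap <- schedule_from_matrix(rbind(matrix(0, 10, 2), matrix(0.01, 20, 2)) |>
                                `colnames<-`(c("a", "other")))
  expect_equal(cumulative_mortality(gap, cause = "a"),
               0.5 * (1 - exp(-0.4)), tolerance = 1e-14)

  neg <- schedule_from_matrix(matrix(c(rep(0.01, 59), -0.01), 30, 2) |>
                                `colnames<-`(c("a", "other")))
  expect_error(cumulative_mortality(neg), class = "lymphrisk_validation_error")
  expect_error(cumulative_mortality(sched[sched$year <= 10, ]),
               class = "lymphrisk_validation_error")
})

test_that("hazard schedules respect layer contracts", {
  rates <- toy_rates()
  cfg <- toy_config()
  quiet <- toy_patient(dose_photon = 6, dose_proton = 2, anthra = 300,
                       smoking = "current")
  bg1 <- build_hazard_schedule(quiet, rates, cfg, layer = "background")
  # background layer ignores doses and chemotherapy entirely
  other_doses <- toy_patient(dose_photon = 20, dose_proton = 11,
                             anthra = 100, smoking = "current")
  bg2 <- build_hazard_schedule(other_doses, rates, cfg, layer = "background")
  expect_equal(bg1, bg2)

  # full layer with null exposure collapses to background
  null_exp <- toy_patient(dose_photon = 0, dose_proton = 0, anthra = 0,
                          smoking = "current")
  expect_equal(
    build_hazard_schedule(null_exp, rates, cfg, layer = "full"),
    build_hazard_schedule(null_exp, rates, cfg, layer = "background")
  )

  # chemotherapy layer leaves second-cancer hazards at background
  chemo <- build_hazard_schedule(quiet, rates, cfg, layer = "chemo")
  for (ep in c("lung_cancer", "breast_cancer", "esophageal_cancer")) {
    expect_equal(chemo$hazard[chemo$cause == ep],
                 bg1$hazard[bg1$cause == ep])
  }
  # but raises heart-failure hazards
  expect_true(all(chemo$hazard[chemo$cause == "heart_failure"] >
                    bg1$hazard[bg1$cause == "heart_failure"]))

  # smoking multiplies the background layer itself
  never <- build_hazard_schedule(
    toy_patient(dose_photon = 6, dose_proton = 2, anthra = 300,
                smoking = "never"),
    rates, cfg, layer = "background"
  )
  expect_equal(bg1$hazard[bg1$cause == "lung_cancer"],
               14 * never$hazard[never$cause == "lung_cancer"])
  # the competing hazard stays at background in every layer
  full <- build_hazard_schedule(quiet, rates, cfg, layer = "full")
  expect_equal(full$hazard[full$cause == "all_other_causes"],
               never$hazard[never$cause == "all_other_causes"])
})

test_that("attained-age lookup uses start-of-year ages within the horizon only", {
  cfg <- toy_config()
  p <- toy_patient(age = 30, dose_photon = 5, dose_proton = 2)
  base <- toy_rates(rate_young = 100, rate_old = 100, split_age = 60)
  # perturb rates only at ages >= 60: a 30-year-old's 30-year window
  # (attained ages 30..59) must not change
  perturbed <- mutate(base,
    rate_per_100k = ifelse(age_lo >= 60, 9999, rate_per_100k))
  d1 <- decompose_patient(p, base, cfg)
  d2 <- decompose_patient(p, validate_rate_table(perturbed), cfg)
  expect_equal(as.data.frame(d1), as.data.frame(d2))

  # but a change inside the window does matter
  inside <- toy_rates(rate_young = 100, rate_old = 100, split_age = 59)
  inside <- mutate(inside,
    rate_per_100k = ifelse(age_lo >= 59, 9999, rate_per_100k))
  d3 <- decompose_patient(p, validate_rate_table(inside), cfg)
  expect_false(isTRUE(all.equal(as.data.frame(d1), as.data.frame(d3))))
})

test_that("patient decomposition has exact null collapse and modality symmetry", {
  rates <- toy_rates()
  cfg <- toy_config()
  # never-smoker, zero chemo, zero dose: every excess is exactly zero
  null_p <- toy_patient(dose_photon = 0, dose_proton = 0, anthra = 0)
  d0 <- decompose_patient(null_p, rates, cfg)
  expect_identical(d0$amr30_background, d0$amr30_full_photon)
  expect_true(all(d0$excess_chemo == 0))
  expect_true(all(d0$excess_rt_photon == 0))

  # equal doses in both modalities give identical radiation excesses
  eq <- decompose_patient(toy_patient(dose_photon = 7, dose_proton = 7,
                                      anthra = 300), rates, cfg)
  expect_equal(eq$excess_rt_photon, eq$excess_rt_proton)

  # componentwise-dominated proton doses give lower risks for every
  # endpoint with a positive dose-response; other_cardiac (ERR 0) can move
  # the opposite way inside the joint cardiovascular table because only its
  # competitors' hazards fall
  dom <- decompose_patient(toy_patient(dose_photon = 10, dose_proton = 4,
                                       anthra = 300), rates, cfg)
  responsive <- dom$endpoint != "other_cardiac"
  expect_true(all(dom$amr30_full_proton[responsive] <
                    dom$amr30_full_photon[responsive]))
  g <- group_decomposition(dom)
  expect_true(all(g$amr30_full_proton < g$amr30_full_photon))
})

test_that("risk components stay within probability bounds", {
  rates <- us_rates()
  cfg <- toy_config()
  cohort <- simulate_cohort(cohort_sim_spec(n_patients = 15, seed = 9))
  d <- decompose_cohort(cohort, rates, cfg)
  cols <- c("amr30_background", "amr30_chemo", "amr30_full_photon",
            "amr30_full_proton")
  for (cl in cols) {
    expect_true(all(d[[cl]] >= 0 & d[[cl]] <= 1))
  }
  # total modeled mortality cannot exceed the patient's all-cause mortality
  tot <- d |> group_by(id) |> summarise(s = sum(amr30_full_photon))
  expect_true(all(tot$s <= 1))
})

test_that("additive-ERR combination mode differs from multiplicative as specified", {
  rates <- toy_rates()
  cfg <- toy_config()
  p <- toy_patient(dose_photon = 10, dose_proton = 10, anthra = 300)
  mult <- build_hazard_schedule(p, rates, cfg, layer = "full",
                                combination = "multiplicative")
  addi <- build_hazard_schedule(p, rates, cfg, layer = "full",
                                combination = "additive_err")
  bg <- build_hazard_schedule(p, rates, cfg, layer = "background")
  hf_m <- mult$hazard[mult$cause == "heart_failure"][1]
  hf_a <- addi$hazard[addi$cause == "heart_failure"][1]
  hf_b <- bg$hazard[bg$cause == "heart_failure"][1]
  # chemo RR 2.6 at 300 mg/m2, radiation factor 1 + 0.10 * 10 = 2
  expect_equal(hf_m / hf_b, 2.6 * 2, tolerance = 1e-12)
  expect_equal(hf_a / hf_b, 1 + 1.6 + 1, tolerance = 1e-12)
})

test_that("treatment latency delays the excess layers", {
  rates <- toy_rates()
  cfg <- toy_config()
  p <- toy_patient(dose_photon = 10, dose_proton = 2, anthra = 300)
  lagged <- build_hazard_schedule(p, rates, cfg, layer = "full", latency = 5)
  bg <- build_hazard_schedule(p, rates, cfg, layer = "background")
  full <- build_hazard_schedule(p, rates, cfg, layer = "full")
  early <- lagged$year <= 5
  expect_equal(lagged$hazard[early], bg$hazard[early])
  expect_equal(lagged$hazard[!early], full$hazard[!early])
})

test_that("direct standardization satisfies the composition identity", {
  # two strata, risks 0.02 / 0.06, equal weights -> 0.04
  df <- tibble(age_band = c("[20,30)", "[30,40)"), sex = "female",
               amr = c(0.02, 0.06))
  std <- tibble(age_band = c("[20,30)", "[30,40)"), sex = "female",
                weight = c(0.5, 0.5))
  expect_equal(standardize(df, "amr", std)$standardized_mean, 0.04)
  # all weight on one stratum returns that stratum's mean
  std1 <- mutate(std, weight = c(1, 0))
  expect_equal(standardize(df, "amr", std1)$standardized_mean, 0.02)

  # subgroup with the standard's own composition: standardized == crude
  set.seed(21)
  big <- tibble(
    age_band = rep(c("[20,30)", "[30,40)", "[40,50)"), each = 40),
    sex = rep(c("male", "female"), 60),
    amr = runif(120, 0, 0.2)
  )
  std_big <- count(big, age_band, sex) |> mutate(weight = n / sum(n))
  res <- standardize(big, "amr", std_big)
  expect_equal(res$standardized_mean, res$crude_mean, tolerance = 1e-12)
  expect_false(res$flagged)

  # empty positive-weight stratum flags and yields NA unless renormalized
  sub <- filter(big, age_band != "[40,50)")
  res2 <- standardize(sub, "amr", std_big)
  expect_true(res2$flagged)
  expect_true(is.na(res2$standardized_mean))
  res3 <- standardize(sub, "amr", std_big, renormalize = TRUE)
  expect_true(res3$flagged)
  expect_false(is.na(res3$standardized_mean))
})

test_that("scenario projections respond to smoking and dose presets", {
  rates <- us_rates()
  cfg <- toy_config()
  doses <- c(whole_heart = 13, left_ventricle = 6, aortic_valve = 16,
             mitral_valve = 16, tricuspid_valve = 16, lungs = 7)
  smoker <- scenario_risk(30, "male", "current", doses, doses * 0.7, 300,
                          rates, cfg)
  never <- scenario_risk(30, "male", "never", doses, doses * 0.7, 300,
                         rates, cfg)
  for (ep in c("coronary_heart_disease", "lung_cancer")) {
    expect_gt(smoker$amr30_full_photon[smoker$endpoint == ep],
              never$amr30_full_photon[never$endpoint == ep])
  }
  # smoking multiplies treatment excess too (full multiplicative transport)
  expect_gt(smoker$excess_rt_photon[smoker$endpoint == "lung_cancer"],
            never$excess_rt_photon[never$endpoint == "lung_cancer"])

  cohort <- simulate_cohort(cohort_sim_spec(n_patients = 30, seed = 5))
  preset <- dose_preset(cohort, "ge40_overlap_means")
  expect_named(preset, c("photon", "proton"))
  expect_true(all(c("whole_heart", "left_ventricle", "lungs") %in%
                    names(preset$photon)))
  lab <- classify_subgroups(cohort)
  manual <- mean(lab$whole_heart[lab$overlap == "ge40" &
                                   lab$modality == "photon"])
  expect_equal(unname(preset$photon["whole_heart"]), manual)
  expect_error(dose_preset(cohort, "nope"), "ge40_overlap_means",
               class = "lymphrisk_validation_error")
})
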