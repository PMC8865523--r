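test_that("the bundled config loads with every endpoint mapped once", {
  cfg <- load_config(system.file("extdata", "dose_response.json",
                                 package = "lymphrisk"))
  expect_s3_class(cfg, "lymphrisk_config")
  expect_length(cfg$endpoints, 8)
  mm <- dose_metric_map(cfg)
  expect_setequal(mm$endpoint, ALL_ENDPOINTS)
  expect_equal(mm$dose_metric[mm$endpoint == "valvular_heart_disease"],
               "sum_valve")
})

test_that("config validation rejects structural defects", {
  cfg <- toy_config()
  broken <- unclass(cfg)
  broken$endpoints$stroke <- NULL
  expect_error(validate_config(broken), "stroke",
               class = "lymphrisk_validation_error")

  expect_error(
    toy_config(list(stroke = list(dose_metric = "spleen", err_per_gy = 0))),
    "spleen", class = "lymphrisk_schema_error"
  )
  # an ERR that can push the rate factor below zero inside the sanity range
  expect_error(
    toy_config(list(stroke = list(dose_metric = "carotid_arteries",
                                  err_per_gy = -0.05))),
    class = "lymphrisk_validation_error"
  )
  expect_error(
    toy_config(list(breast_cancer = list(
      dose_metric = "breast", err_per_gy = 0.1,
      age_modifiers = list(list(age_lo = 0, age_hi = 30, err_per_gy = 0.2),
                           list(age_lo = 20, age_hi = 40, err_per_gy = 0.1))
    ))),
    "overlap", class = "lymphrisk_validation_error"
  )
})

test_that("radiation rate factor is linear in dose with age-banded ERRs", {
  cfg <- toy_config()
  doses0 <- as.list(setNames(rep(0, 11),
                             c("whole_heart", "left_ventricle", "sum_valve",
                               "aortic_valve", "mitral_valve",
                               "tricuspid_valve", "carotid_arteries", "lungs",
                               "breast", "esophagus", "normal_tissue")))
  for (ep in ALL_ENDPOINTS) {
    expect_equal(radiation_rate_factor(cfg, ep, doses0, 30), 1)
  }
  d5 <- modifyList(doses0, list(lungs = 5))
  expect_equal(radiation_rate_factor(cfg, "lung_cancer", d5, 30), 1.5)

  # age-modifier band replaces the ERR: 0.30/Gy below 25
  db <- modifyList(doses0, list(breast = 2))
  expect_equal(radiation_rate_factor(cfg, "breast_cancer", db, 24), 1.6)
  expect_equal(radiation_rate_factor(cfg, "breast_cancer", db, 25),
               1 + 0.15 * 2)
  expect_equal(radiation_rate_factor(cfg, "breast_cancer", db, 40),
               1 + 0.05 * 2)

  # affine in dose: excesses add
  f <- function(d) {
    radiation_rate_factor(cfg, "coronary_heart_disease",
                          modifyList(doses0, list(whole_heart = d)), 30)
  }
  set.seed(3)
  for (i in 1:20) {
    d1 <- runif(1, 0, 20); d2 <- runif(1, 0, 20)
    expect_equal(f(d1 + d2) - 1, (f(d1) - 1) + (f(d2) - 1), tolerance = 1e-12)
  }

  expect_error(
    radiation_rate_factor(cfg, "lung_cancer",
                          modifyList(doses0, list(lungs = NULL)), 30),
    "lungs", class = "lymphrisk_validation_error"
  )
})

test_that("chemotherapy factor is banded, CVD-only, and 1 at zero exposure", {
  cfg <- toy_config()
  expect_equal(chemo_rate_factor(cfg, "heart_failure", 0), 1)
  expect_equal(chemo_rate_factor(cfg, "lung_cancer", 350), 1)
  expect_equal(chemo_rate_factor(cfg, "esophageal_cancer", 350), 1)
  expect_equal(chemo_rate_factor(cfg, "heart_failure", 200), 1.7)
  expect_equal(chemo_rate_factor(cfg, "heart_failure", 250), 2.6)
  expect_equal(chemo_rate_factor(cfg, "heart_failure", 340), 2.6)
  expect_equal(chemo_rate_factor(cfg, "coronary_heart_disease", 340), 1.3)
  expect_error(chemo_rate_factor(cfg, "heart_failure", -1),
               class = "lymphrisk_validation_error")
})

test_that("smoking factor uses never-smokers as reference with pooled former smokers", {
  cfg <- toy_config()
  for (ep in ALL_ENDPOINTS) {
    expect_equal(smoking_rate_factor(cfg, ep, "never"), 1)
    expect_equal(smoking_rate_factor(cfg, ep, "unknown"), 1)
  }
  expect_equal(smoking_rate_factor(cfg, "lung_cancer", "current"), 14)
  expect_equal(smoking_rate_factor(cfg, "lung_cancer", "former"), 14)
  # endpoints without a configured ratio default to 1
  expect_equal(smoking_rate_factor(cfg, "esophageal_cancer", "current"), 1)
  # separate former-smoker multiplier honored when configured
  cfg2 <- toy_config(list(lung_cancer = list(
    dose_metric = "lungs", err_per_gy = 0.1, smoking_rr = 14,
    smoking_rr_former = 4
  )))
  expect_equal(smoking_rate_factor(cfg2, "lung_cancer", "former"), 4)
  expect_equal(smoking_rate_factor(cfg2, "lung_cancer", "current"), 14)
})

test_that("all three factors collapse to 1 under null exposure", {
  cfg <- toy_config()
  doses0 <- list(whole_heart = 0, left_ventricle = 0, sum_valve = 0,
                 carotid_arteries = 0, lungs = 0, breast = 0, esophagus = 0,
                 normal_tissue = 0)
  for (ep in ALL_ENDPOINTS) {
    expect_identical(radiation_rate_factor(cfg, ep, doses0, 30), 1)
    expect_identical(chemo_rate_factor(cfg, ep, 0), 1)
    expect_identical(smoking_rate_factor(cfg, ep, "never"), 1)
  }
})
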