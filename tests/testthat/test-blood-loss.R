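test_that("body surface area matches the power-law formula", {
  # both power terms equal 1 at (1, 1), exposing the bare coefficient
  expect_equal(body_surface_area(1, 1), 0.0235)
  # frozen high-precision evaluations of the printed formula
  expect_equal(body_surface_area(170, 70), 1.8312894, tolerance = 1e-6)
  expect_equal(body_surface_area(160, 55), 1.5766722, tolerance = 1e-6)
  expect_error(body_surface_area(0, 70), "positive")
  expect_error(body_surface_area(170, -1), "positive")
})

test_that("BSA is strictly increasing in height and in weight", {
  h <- seq(140, 200, by = 5)
  expect_true(all(diff(body_surface_area(h, 70)) > 0))
  w <- seq(40, 120, by = 5)
  expect_true(all(diff(body_surface_area(170, w)) > 0))
})

test_that("estimated blood volume applies the sex-specific factor", {
  expect_equal(estimated_blood_volume("male", 2.0), 5060)
  expect_equal(estimated_blood_volume("female", 2.0), 4860)
  expect_equal(estimated_blood_volume("female", 1.577), 3832.11)
  expect_error(estimated_blood_volume("other", 1.5), "sex")
  expect_error(estimated_blood_volume("male", 0), "bsa")
})

test_that("rbc_loss decomposes into uncompensated + compensated", {
  x <- rbc_loss(5000, 0.40, 0.35, 0)
  expect_equal(x$uncompensated_ml, 250)
  expect_equal(x$compensated_ml, 0)
  expect_equal(x$total_ml, 250)
  expect_equal(rbc_loss(5000, 0.40, 0.40, 0)$total_ml, 0)
  y <- rbc_loss(3832.1, 0.40, 0.35, 350)
  expect_equal(y$uncompensated_ml, 191.605, tolerance = 1e-4)
  expect_equal(y$total_ml, 541.605, tolerance = 1e-4)
  # hemoconcentration reversal propagates as negative, not clamped
  expect_lt(rbc_loss(5000, 0.35, 0.40, 0)$uncompensated_ml, 0)
  expect_error(rbc_loss(5000, 1.2, 0.35, 0), class = "pcnl_domain_error")
  expect_error(rbc_loss(5000, 0.40, 0, 0), class = "pcnl_domain_error")
})

test_that("total blood loss divides by the mean perioperative hematocrit", {
  expect_equal(total_blood_loss(250, 0.40, 0.35), 250 / 0.375,
               tolerance = 1e-9)
  expect_equal(total_blood_loss(0, 0.40, 0.40), 0)
  expect_equal(total_blood_loss(541.6, 0.40, 0.35), 1444.27,
               tolerance = 0.01)
})

test_that("the full chain reproduces the hand-computed example", {
  coh <- pcnl_cohort(one_patient())  # female, 160 cm, 55 kg, 0.40 -> 0.35
  est <- estimate_blood_loss(coh)
  expect_equal(est$bsa_m2, 1.5766722, tolerance = 1e-6)
  expect_equal(est$ebv_ml, 3831.3135, tolerance = 1e-3)
  expect_equal(est$tbl_ml, 510.84, tolerance = 0.01)
  # same patient with 350 mL whole-blood transfusion
  coh2 <- pcnl_cohort(one_patient(transfused_intraop_ml = 350))
  expect_equal(estimate_blood_loss(coh2)$tbl_ml, 1444.18, tolerance = 0.01)
})

test_that("zero hematocrit shift and no transfusion give zero blood loss", {
  coh <- pcnl_cohort(one_patient(hct_72h = 0.40))
  expect_equal(estimate_blood_loss(coh)$tbl_ml, 0)
})

test_that("male/female TBL ratio is the EBV factor ratio", {
  m <- pcnl_cohort(one_patient(sex = "male"))
  f <- pcnl_cohort(one_patient(sex = "female"))
  expect_equal(estimate_blood_loss(m)$tbl_ml / estimate_blood_loss(f)$tbl_ml,
               2530 / 2430, tolerance = 1e-12)
})

test_that("TBL is invariant to a common hematocrit rescaling when untransfused", {
  set.seed(42)
  for (i in 1:50) {
    h1 <- runif(1, 0.30, 0.45)
    h2 <- h1 - runif(1, 0.01, 0.10)
    cc <- runif(1, 0.5, 1.3)
    base <- total_blood_loss(rbc_loss(4500, h1, h2, 0)$total_ml, h1, h2)
    scaled <- total_blood_loss(rbc_loss(4500, cc * h1, cc * h2, 0)$total_ml,
                               cc * h1, cc * h2)
    expect_equal(scaled, base, tolerance = 1e-9)
  }
})

test_that("TBL increases with the hematocrit drop and with transfusion", {
  # fixed mean hematocrit 0.375, growing drop
  drops <- seq(0.0, 0.10, by = 0.01)
  tbl <- vapply(drops, function(d) {
    h1 <- 0.375 + d / 2; h2 <- 0.375 - d / 2
    total_blood_loss(rbc_loss(4500, h1, h2, 0)$total_ml, h1, h2)
  }, numeric(1))
  expect_true(all(diff(tbl) > 0))
  vols <- seq(0, 1000, by = 100)
  tbl2 <- vapply(vols, function(v) {
    total_blood_loss(rbc_loss(4500, 0.40, 0.35, v)$total_ml, 0.40, 0.35)
  }, numeric(1))
  expect_true(all(diff(tbl2) > 0))
})

test_that("records without a 72-h draw are excluded or abort, as configured", {
  df <- rbind(one_patient(),
              one_patient(patient_id = "p2", hct_72h = NA_real_,
                          hct_24h = 0.36))
  coh <- pcnl_cohort(df)
  expect_message(est <- estimate_blood_loss(coh), "p2")
  expect_equal(nrow(est), 1)
  expect_identical(attr(est, "excluded"), "p2")
  expect_error(estimate_blood_loss(coh, on_missing = "error"),
               class = "pcnl_estimation_error")
})
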