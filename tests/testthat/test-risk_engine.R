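test_that("cox survival form reduces to 1 - S0 at zero linear predictor", {
  co <- structure(list(
    age_range = c(30, 74), chd_stroke_split = 0.75,
    male = list(coefficients = list(ln_age = 0, ln_total_cholesterol = 0,
                                    ln_hdl = 0, ln_sbp_untreated = 0,
                                    smoker = 0, diabetic = 0),
                mean_lp = 0, baseline_survival = 0.9),
    female = list(coefficients = list(ln_age = 0, ln_total_cholesterol = 0,
                                      ln_hdl = 0, ln_sbp_untreated = 0,
                                      smoker = 0, diabetic = 0),
                  mean_lp = 0, baseline_survival = 0.9)
  ), class = "irapen_risk_coeffs")
  prof <- paper_base_case("low", FALSE)$profile
  expect_equal(ten_year_risk(prof, co), 0.1)
})

test_that("packaged profiles land in their own risk bands (self-consistency)", {
  co <- load_risk_coefficients()
  for (d in c(FALSE, TRUE)) {
    for (lab in c("low", "moderate", "high", "very_high")) {
      prof <- paper_base_case(lab, d)$profile
      r <- ten_year_risk(prof, co)
      expect_identical(classify_who_ish(r), lab,
                       label = sprintf("%s (diabetic=%s) risk %.3f", lab, d, r))
    }
  }
  # band extremes from the program definition
  vh <- paper_base_case("very_high", FALSE)$profile
  expect_gte(ten_year_risk(vh, co), 0.30)
  lo <- paper_base_case("low", FALSE)$profile
  expect_lt(ten_year_risk(lo, co), 0.10)
})

test_that("10-year risk is monotone in each risk factor", {
  co <- load_risk_coefficients()
  set.seed(42)
  base <- paper_base_case("moderate", FALSE)$profile
  for (i in 1:25) {
    prof <- base
    prof$sbp <- runif(1, 120, 200)
    prof$total_cholesterol <- runif(1, 150, 380)
    prof$hdl <- runif(1, 30, 70)
    prof$age_entry <- sample(35:70, 1)
    prof$sex <- sample(c("male", "female"), 1)
    prof$smoker <- runif(1) < 0.5
    r0 <- ten_year_risk(prof, co)
    up <- prof; up$sbp <- prof$sbp + 10
    expect_gt(ten_year_risk(up, co), r0)
    up <- prof; up$total_cholesterol <- prof$total_cholesterol + 20
    expect_gt(ten_year_risk(up, co), r0)
    up <- prof; up$age_entry <- prof$age_entry + 2
    expect_gt(ten_year_risk(up, co), r0)
    if (!prof$smoker) {
      up <- prof; up$smoker <- TRUE
      expect_gt(ten_year_risk(up, co), r0)
    }
  }
})

test_that("ages outside the equation range are clamped with a warning", {
  co <- load_risk_coefficients()
  prof <- paper_base_case("low", FALSE)$profile
  expect_warning(r80 <- ten_year_risk(prof, co, age = 80), "clamped")
  expect_equal(r80, ten_year_risk(prof, co, age = 74))
  expect_silent(ten_year_risk(prof, co, age = 80, warn_clamp = FALSE))
})

test_that("annual probability conversion follows the constant-hazard form", {
  expect_equal(annual_probability(0), 0)
  # oracle: direct evaluation of 1 - (1 - p10)^(1/10)
  expect_equal(annual_probability(0.10), 1 - 0.9^0.1)
  expect_equal(annual_probability(0.10), 0.010481, tolerance = 1e-4)
  expect_equal(annual_probability(0.30), 1 - 0.7^0.1)
  expect_equal(annual_probability(0.30), 0.035040, tolerance = 1e-4)
  p <- seq(0, 0.95, by = 0.05)
  expect_true(all(annual_probability(p) <= p))
  expect_error(annual_probability(1), "\\[0, 1\\)")
})

test_that("WHO/ISH classification is total, half-open and monotone", {
  expect_identical(classify_who_ish(0.05), "low")
  expect_identical(classify_who_ish(0.10), "moderate")  # boundary belongs above
  expect_identical(classify_who_ish(0.1999), "moderate")
  expect_identical(classify_who_ish(0.20), "high")
  expect_identical(classify_who_ish(0.30), "very_high")
  expect_identical(classify_who_ish(0.35), "very_high")
  expect_identical(classify_who_ish(c(0, 1)), c("low", "very_high"))
  # piecewise-constant and monotone over a grid
  g <- seq(0, 1, by = 0.001)
  labs <- classify_who_ish(g)
  ord <- match(labs, c("low", "moderate", "high", "very_high"))
  expect_true(all(diff(ord) >= 0))
  # classification always uses the 10-year risk: annualizing first would
  # change the band, so the map is applied before any conversion
  expect_identical(classify_who_ish(0.30), "very_high")
  expect_identical(classify_who_ish(annual_probability(0.30)), "low")
})

test_that("net background mortality subtracts CVD-attributable deaths", {
  lt <- data.frame(age = 50, qx = 0.01)
  expect_equal(net_background_mortality(50, lt, 0.0), 0.01)
  expect_equal(net_background_mortality(50, lt, 0.004), 0.006)
  expect_error(net_background_mortality(50, lt, 0.012), "exceeds")
  expect_error(net_background_mortality(60, lt, 0), "not covered")
  cvd <- data.frame(age = 50, qx_cvd = 0.003)
  expect_equal(net_background_mortality(50, lt, cvd), 0.007)
})
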