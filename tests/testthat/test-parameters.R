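test_that("cost component sums reproduce the published per-cohort rial totals", {
  tab <- base_case_tables()
  for (lab in c("low", "moderate", "high")) {
    cc <- tab$cohort_costs[[lab]]
    expect_identical(sum_cost_components(unlist(cc$components_irr)),
                     cc$total_irr_printed + 0)
  }
  # the very-high column's printed total exceeds its component sum by 1 IRR
  vh <- tab$cohort_costs$very_high
  expect_identical(sum_cost_components(unlist(vh$components_irr)),
                   vh$total_irr_printed - 1)
  expect_identical(sum_cost_components(numeric()), 0)
  expect_error(sum_cost_components(c(10, -1)), "non-negative")
})

test_that("rial-to-dollar adjustment follows the implied inflation and exchange factors", {
  expect_equal(adjust_cost(165804, 1.0, 165804), 1.0)
  # oracle: direct arithmetic on the implied factor pair
  f <- 216540 / 165804
  x <- 216540 / 5.16
  expect_equal(adjust_cost(165804, f, x), 5.16)
  expect_equal(adjust_cost(0, 1.306, 41965), 0)
  expect_error(adjust_cost(100, 0, 41965), "inflation")
  expect_error(adjust_cost(100, 1.306, -1), "exchange")
  # packaged conversion constants are exactly the implied pair
  cv <- base_case_tables()$currency_conversion
  expect_equal(cv$inflation_factor, f)
  expect_equal(cv$exchange_rate_irr_per_usd, x)
})

test_that("the packaged base case carries the published values and provenance", {
  p <- paper_base_case("very_high", TRUE)
  expect_equal(p$costs$program_annual_cost, 85.29)
  expect_equal(p$profile$sex, "male")
  expect_true(p$profile$smoker)
  expect_equal(paper_base_case("low", TRUE)$costs$program_annual_cost, 21.63)
  expect_equal(paper_base_case("high", TRUE)$costs$stroke_cost_year1, 5691)
  expect_equal(p$utilities$u_chd_year1, 0.67)
  expect_equal(p$utilities$u_stroke_year1, 0.33)
  expect_equal(p$economics$wtp_threshold, 4091)
  expect_equal(p$mortality$chd_case_fatality_year1, 0.25)
  expect_identical(unname(p$provenance["mortality/background_life_table"]), "synthetic")
  expect_identical(unname(p$provenance["utilities"]), "printed")
  expect_error(paper_base_case("extreme", TRUE), "unknown")
})

test_that("every packaged cohort scenario passes the full validation suite", {
  for (d in c(FALSE, TRUE)) {
    for (lab in c("low", "moderate", "high", "very_high")) {
      expect_no_error(validate_parameters(paper_base_case(lab, d)))
    }
  }
})

test_that("parameter sets round-trip through serialization exactly", {
  for (args in list(list("low", FALSE), list("very_high", TRUE))) {
    p <- paper_base_case(args[[1]], args[[2]])
    f <- withr::local_tempfile(fileext = ".json")
    save_parameters(p, f)
    q <- load_parameters(f)
    expect_equal(q, p)
    # and a second round trip is bit-stable
    f2 <- withr::local_tempfile(fileext = ".json")
    save_parameters(q, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("config loading fills gaps from the base case and rejects invariant violations", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("profile:", "  cohort_label: moderate", "  diabetic: yes",
               "economics:", "  adherence: 0.5"), f)
  p <- load_parameters(f)
  expect_equal(p$economics$adherence, 0.5)
  expect_equal(p$costs$program_annual_cost, 57.46)  # filled from base case
  expect_equal(p$utilities$u_chd_year1, 0.67)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("profile:", "  cohort_label: moderate", "  diabetic: no",
               "utilities:", "  u_dead: 0.1"), bad)
  expect_error(load_parameters(bad), "u_dead")
  expect_error(load_parameters("missing_file.yaml"), "not found")
})

test_that("life tables load from two-column CSV", {
  lt <- load_life_table_csv(system.file("extdata", "example_life_table.csv",
                                        package = "irapen"))
  expect_named(lt, c("age", "qx"))
  expect_equal(lt$age[1], 40)
  expect_true(all(lt$qx > 0 & lt$qx < 1))
})

test_that("type constructors reject out-of-contract inputs naming the field", {
  expect_error(risk_profile("low", 25, "male", c(120, 139), 130,
                            c(100, 195), 180, 40, FALSE, FALSE), "age_entry")
  expect_error(treatment_effect("x", 0.9, c(0.95, 1.0), 0.9, c(0.8, 1.0)),
               "outside its CI")
  p <- paper_base_case("low", FALSE)
  p$costs$chd_cost_year1 <- 100  # below the chronic cost
  expect_error(validate_parameters(p), "chd_cost_year1")
})
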