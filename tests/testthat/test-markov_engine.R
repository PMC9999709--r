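test_that("cycle transitions scale baselines by the arm's relative risks", {
  p <- paper_base_case("moderate", FALSE)
  p$risk$mode <- "fixed"
  p$annual_incidence_chd <- 0.02
  ct <- build_cycle_transitions(40, p, rr_chd = 0.75728, rr_stroke = 1)
  expect_equal(ct$p_chd_event, 0.02 * 0.75728)  # direct product
  # null intervention equals the status-quo transition set
  ct1 <- build_cycle_transitions(40, p, 1, 1)
  ct0 <- build_cycle_transitions(40, p, 1, 1)
  expect_identical(ct1, ct0)
  expect_error(build_cycle_transitions(200, p, 1, 1), "not covered")
  p$annual_incidence_chd <- 0.9
  p$annual_incidence_stroke <- 0.2
  expect_error(build_cycle_transitions(40, p, 1, 1), "sum to > 1")
})

test_that("an event-free cohort with no hazards never leaves the first state", {
  p <- degenerate_params()
  tr <- run_cohort(p, "irapen")
  expect_equal(nrow(tr), 41)
  expect_true(all(tr$event_free == 1))
  expect_true(all(tr$dead == 0))
})

test_that("tunnel mechanics: one cycle in the first-year state, then chronic", {
  p <- degenerate_params()
  p$annual_incidence_chd <- 0.999999  # (sum with stroke+bg must stay < 1)
  p$annual_incidence_chd <- 0.99
  tr <- run_cohort(p, "status_quo")
  expect_equal(tr$chd_year1[2], 0.99)          # entrants occupy the tunnel
  expect_equal(tr$chd_post[3], 0.99 * 0.99 + 0.99 * 0.01,
               tolerance = 1e-12)              # prior tunnel+post move to chronic
  expect_equal(tr$chd_year1[3], 0.01 * 0.99)  # only fresh entrants
  # no return to event-free, no cross-event transitions
  expect_true(all(diff(tr$event_free) <= 0))
  expect_true(all(tr$stroke_year1 == 0) && all(tr$stroke_post == 0))
})

test_that("occupancy is conserved and death is absorbing on real scenarios", {
  for (seed in 1:4) {
    sc <- make_scenario(seed, sample(c("moderate", "high", "very_high"), 1))
    for (arm in c("status_quo", "irapen")) {
      tr <- run_cohort(sc$params, arm)
      expect_conserved(tr)
      expect_true(all(diff(tr$dead) >= -1e-15))
      expect_true(all(as.matrix(tr[, -1]) >= -1e-15))
      # cause accounting equals the flow into dead each cycle
      flow <- diff(tr$dead)
      acct <- (tr$fatal_chd_prehospital + tr$fatal_chd_hospital +
                 tr$fatal_stroke_early + tr$other_death)[-1]
      expect_equal(acct, flow, tolerance = 1e-12)
    }
  }
})

test_that("zero-hazard runs reproduce the annuity closed form", {
  C <- 57.46
  p <- degenerate_params(program_cost = C, discount = 0)
  out <- accumulate_outcomes(run_cohort(p, "irapen"), p)
  expect_equal(out$cost, 40 * C)
  expect_equal(out$qaly, 40)
  expect_equal(out$ly, 40)
  p <- degenerate_params(program_cost = C, discount = 0.035)
  out <- accumulate_outcomes(run_cohort(p, "irapen"), p)
  expect_equal(out$cost, C * annuity(0.035, 40))
  expect_equal(annuity(0.035, 40), 21.3551, tolerance = 1e-4)
  # status quo: event-free occupancy is costless
  sq <- accumulate_outcomes(run_cohort(p, "status_quo"), p, "status_quo")
  expect_equal(sq$cost, 0)
})

test_that("fatal-event costing follows the prehospital and 40%-cycle-cost rules", {
  p <- degenerate_params(program_cost = 0, discount = 0)
  p$annual_incidence_chd <- 0.1
  p$annual_incidence_stroke <- 0.1
  p$mortality$chd_case_fatality_year1 <- 1  # every event fatal
  p$mortality$stroke_case_fatality_year1 <- 1
  p$economics$horizon_cycles <- 1
  p$mortality$background_life_table <-
    p$mortality$background_life_table[1:2, ]
  tr <- run_cohort(p, "status_quo")
  out <- accumulate_outcomes(tr, p, "status_quo")
  # CHD deaths: only the in-hospital 40% incur the first-year cost;
  # stroke deaths incur 40% of the first-year cost
  expect_equal(out$cost,
               0.1 * 0.4 * p$costs$chd_cost_year1 +
                 0.1 * 0.4 * p$costs$stroke_cost_year1)
  # fatal entrants accrue no QALY or LY in their event cycle
  expect_equal(out$qaly, 0.8 * 1)
  expect_equal(out$ly, 0.8)
})

test_that("null intervention with zero program cost is outcome-identical across arms", {
  sc <- make_scenario(5, "high")
  p <- sc$params
  for (t in names(p$treatments)) {
    p$treatments[[t]]$rr_chd <- 1
    p$treatments[[t]]$rr_chd_ci <- c(1, 1)
    p$treatments[[t]]$rr_stroke <- 1
    p$treatments[[t]]$rr_stroke_ci <- c(1, 1)
  }
  p$costs$program_annual_cost <- 0
  res <- run_cea(p)
  expect_identical(res$delta_cost, 0)
  expect_identical(res$delta_qaly, 0)
  expect_identical(res$delta_ly, 0)
})

test_that("life years dominate QALYs and discounting never increases outcomes", {
  for (seed in 1:3) {
    sc <- make_scenario(seed + 10, "very_high", diabetic = (seed %% 2 == 0))
    for (arm in c("status_quo", "irapen")) {
      out <- run_arm(sc$params, arm)
      expect_gte(out$ly, out$qaly)
      expect_gte(out$ly_undiscounted, out$ly)
      expect_gte(out$qaly_undiscounted, out$qaly)
      expect_gte(out$cost_undiscounted, out$cost)
    }
  }
})

test_that("strengthening the intervention weakly increases incremental QALYs", {
  sc <- make_scenario(21, "high")
  base <- run_cea(sc$params)
  p2 <- sc$params
  p2$treatments$statin$rr_chd <- 0.70
  p2$treatments$statin$rr_chd_ci <- c(0.6, 0.8)
  stronger <- run_cea(p2)
  expect_gte(stronger$delta_qaly, base$delta_qaly)
})

test_that("trace export is deterministic and byte-identical across reruns", {
  sc <- make_scenario(3, "moderate")
  tr <- run_cohort(sc$params, "irapen")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_trace(tr, f1)
  export_trace(run_cohort(sc$params, "irapen"), f2)
  expect_identical(readLines(f1), readLines(f2))
})
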