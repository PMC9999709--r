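test_that("distribution fitting recovers the input moments", {
  # gamma: cost mean 519, SE 51.9 -> shape 100, rate 0.192678 (moment matching)
  d <- fit_distribution("costs/chd_cost_year1", "gamma", mean = 519, se = 51.9)
  expect_equal(d$hyper$shape, 100)
  expect_equal(d$hyper$rate, 519 / 51.9^2)
  expect_equal(dist_mean(d), 519, tolerance = 1e-9)
  # beta: utility mean recovered within 1e-9
  d <- fit_distribution("utilities/u_chd_year1", "beta", mean = 0.67, se = 0.024)
  expect_equal(dist_mean(d), 0.67, tolerance = 1e-9)
  # lognormal CI inversion: the point estimate is the median
  d <- fit_distribution("treatments/statin/rr_chd", "lognormal_from_ci",
                        rr = 0.86, ci_low = 0.82, ci_high = 0.90)
  expect_equal(exp(d$hyper$meanlog), 0.86)
  expect_equal(d$hyper$sdlog, (log(0.90) - log(0.82)) / (2 * 1.959964))
  expect_error(fit_distribution("x", "beta", mean = 0.5, se = 0.9), "infeasible")
  expect_error(fit_distribution("x", "gamma", mean = -1, se = 1), "mean")
})

test_that("sample means converge to the deterministic means", {
  n <- 1e5
  cases <- list(
    fit_distribution("a", "gamma", mean = 519, se = 51.9),
    fit_distribution("b", "beta", mean = 0.67, se = 0.024),
    fit_distribution("c", "lognormal_from_ci", rr = 0.86,
                     ci_low = 0.82, ci_high = 0.90)
  )
  set.seed(4242)
  for (d in cases) {
    x <- irapen:::.sample_dist(d, n)
    se_mean <- stats::sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - dist_mean(d)), 3 * se_mean)
  }
})

test_that("degenerate distributions collapse the PSA onto the deterministic result", {
  sc <- make_scenario(61, "very_high")
  det <- run_cea(sc$params)
  assignments <- list(
    "costs/chd_cost_year1" = fit_distribution("costs/chd_cost_year1", "gamma",
                                              mean = sc$params$costs$chd_cost_year1, se = 0),
    "utilities/u_chd_year1" = fit_distribution("utilities/u_chd_year1", "beta",
                                               mean = 0.67, se = 0),
    "treatments/statin/rr_chd" = fit_distribution("treatments/statin/rr_chd",
                                                  "lognormal_from_ci", rr = 0.86,
                                                  ci_low = 0.86, ci_high = 0.86)
  )
  psa <- run_psa(sc$params, n_draws = 5, seed = 7, assignments = assignments)
  expect_true(all(psa$samples$delta_cost == det$delta_cost))
  expect_true(all(psa$samples$delta_qaly == det$delta_qaly))
})

test_that("identical seeds give bit-identical PSA summaries", {
  sc <- make_scenario(62, "high")
  p1 <- run_psa(sc$params, n_draws = 40, seed = 123)
  p2 <- run_psa(sc$params, n_draws = 40, seed = 123)
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$summary, p2$summary)
  p3 <- run_psa(sc$params, n_draws = 40, seed = 124)
  expect_false(identical(p1$samples$delta_cost, p3$samples$delta_cost))
})

test_that("named substreams isolate each parameter's draws", {
  sc <- make_scenario(63, "moderate")
  a_full <- default_psa_assignments(sc$params)
  a_sub <- a_full[setdiff(names(a_full), "utilities/u_stroke_year1")]
  p_full <- run_psa(sc$params, n_draws = 25, seed = 9, assignments = a_full)
  p_sub <- run_psa(sc$params, n_draws = 25, seed = 9, assignments = a_sub)
  shared <- colnames(p_sub$draws)
  expect_identical(p_full$draws[, shared], p_sub$draws[, shared])
})

test_that("the CEAC is monotone and hits its limiting values", {
  sc <- make_scenario(64, "very_high")
  psa <- run_psa(sc$params, n_draws = 60, seed = 5)
  grid <- seq(0, 20000, by = 500)
  curve <- ceac(psa, grid)
  expect_equal(curve$probability_cost_effective[1],
               mean(psa$samples$delta_cost < 0))
  if (all(psa$samples$delta_qaly > 0)) {
    expect_true(all(diff(curve$probability_cost_effective) >= 0))
    expect_equal(curve$probability_cost_effective[nrow(curve)], 1)
  }
  # degenerate single-sample curve: always cost-effective when dominant
  one <- data.frame(delta_cost = -52, delta_qaly = 1.19)
  expect_true(all(ceac(one, c(0, 1000, 4091))$probability_cost_effective == 1))
  expect_error(ceac(psa, numeric()), "non-empty")
})
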