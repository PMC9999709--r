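# shared fixtures, built in code

base_low_nodiab <- function() paper_base_case("low", FALSE)

# degenerate diagnostic configuration: no events, no deaths, known program
# cost; bypasses the life-table positivity invariant on purpose (closed-form
# checks need an exactly immortal cohort)
degenerate_params <- function(program_cost = 10, discount = 0.035) {
  p <- paper_base_case("low", FALSE)
  p$mortality$background_life_table$qx <- rep(0, nrow(p$mortality$background_life_table))
  p$mortality$post_chd_annual_fatality <- 0
  p$mortality$post_stroke_annual_fatality <- 0
  p$mortality$chd_case_fatality_year1 <- 0
  p$mortality$stroke_case_fatality_year1 <- 0
  p$annual_incidence_chd <- 0
  p$annual_incidence_stroke <- 0
  p$risk$mode <- "fixed"
  p$costs$program_annual_cost <- program_cost
  p$economics$discount_rate_costs <- discount
  p$economics$discount_rate_effects <- discount
  p
}

# annuity factor sum_{t=1..n} (1+r)^-t
annuity <- function(r, n) if (r == 0) n else (1 - (1 + r)^(-n)) / r

expect_conserved <- function(trace, tol = 1e-12) {
  occ <- rowSums(trace[, c("event_free", "chd_year1", "chd_post",
                           "stroke_year1", "stroke_post", "dead")])
  expect_true(all(abs(occ - 1) < tol))
}
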