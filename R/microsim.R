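# Independent individual-level microsimulation of the same natural
# history and reward rules as the cohort engine. Used as a validation
# oracle: means over simulees must agree with the cohort trace within
# Monte-Carlo error. Implemented directly from the parameter set (its own
# transition arithmetic, not the cohort engine's), vectorized over
# individuals.

#' Individual-level microsimulation of one arm
#'
#' Simulates `n` individuals through the annual cycles, sampling each
#' transition (event type, first-year fatality with prehospital split,
#' post-event death, background death) per individual, and accumulates
#' the same discounted rewards the cohort engine defines. Returns
#' per-individual totals plus their means and Monte-Carlo standard
#' errors.
#'
#' @param params a validated `irapen_params` object
#' @param arm `"status_quo"` or `"irapen"`
#' @param n number of simulated individuals
#' @param seed RNG seed
#' @return list: `mean` (cost, qaly, ly — discounted), `mc_se`
#'   (standard errors of those means), `n`, and `totals` (n x 3 matrix)
#' @export
microsimulate <- function(params, arm = c("status_quo", "irapen"),
                          n = 1e5, seed = 1) {
  arm <- match.arg(arm)
  set.seed(seed)
  H <- params$economics$horizon_cycles
  rr <- .arm_rrs(params, arm)
  co <- params$costs
  u <- params$utilities
  m <- params$mortality
  lt <- m$background_life_table
  program_cost <- if (arm == "irapen") co$program_annual_cost else co$status_quo_eventfree_cost
  dc <- (1 + params$economics$discount_rate_costs)^(-(1:H))
  de <- (1 + params$economics$discount_rate_effects)^(-(1:H))

  # states: 1 event_free, 2 chd_year1, 3 chd_post, 4 stroke_year1,
  # 5 stroke_post, 6 dead
  state <- rep(1L, n)
  cost <- qaly <- ly <- numeric(n)
  for (t in seq_len(H)) {
    age <- params$profile$age_entry + t - 1L
    base <- baseline_event_probs(params, age)
    p_chd <- base[["chd"]] * rr[["chd"]]
    p_stroke <- base[["stroke"]] * rr[["stroke"]]
    q_bg <- lt$qx[match(age, lt$age)]
    p_die_chd <- 1 - (1 - m$post_chd_annual_fatality) * (1 - q_bg)
    p_die_stroke <- 1 - (1 - m$post_stroke_annual_fatality) * (1 - q_bg)

    new_state <- state
    alive <- state != 6L

    ef <- which(state == 1L)
    if (length(ef)) {
      r <- runif(length(ef))
      chd_ev <- r < p_chd
      stroke_ev <- !chd_ev & r < p_chd + p_stroke
      oth <- !chd_ev & !stroke_ev & r < p_chd + p_stroke + q_bg
      # CHD events: 25% fatal, of which 60% prehospital (costless)
      idx <- ef[chd_ev]
      if (length(idx)) {
        fatal <- runif(length(idx)) < m$chd_case_fatality_year1
        prehosp <- runif(length(idx)) < co$prehospital_chd_death_fraction
        new_state[idx] <- ifelse(fatal, 6L, 2L)
        cost[idx] <- cost[idx] + dc[t] * ifelse(
          fatal, ifelse(prehosp, 0, co$chd_cost_year1), co$chd_cost_year1)
        qaly[idx] <- qaly[idx] + de[t] * ifelse(fatal, 0, u$u_chd_year1)
        ly[idx] <- ly[idx] + de[t] * ifelse(fatal, 0, 1)
      }
      idx <- ef[stroke_ev]
      if (length(idx)) {
        fatal <- runif(length(idx)) < m$stroke_case_fatality_year1
        new_state[idx] <- ifelse(fatal, 6L, 4L)
        cost[idx] <- cost[idx] + dc[t] * ifelse(
          fatal, co$fatal_stroke_cost_fraction * co$stroke_cost_year1, co$stroke_cost_year1)
        qaly[idx] <- qaly[idx] + de[t] * ifelse(fatal, 0, u$u_stroke_year1)
        ly[idx] <- ly[idx] + de[t] * ifelse(fatal, 0, 1)
      }
      idx <- ef[oth]
      if (length(idx)) new_state[idx] <- 6L
      idx <- ef[!chd_ev & !stroke_ev & !oth]
      if (length(idx)) {
        cost[idx] <- cost[idx] + dc[t] * program_cost
        qaly[idx] <- qaly[idx] + de[t] * u$u_healthy
        ly[idx] <- ly[idx] + de[t]
      }
    }

    for (spec in list(list(from = c(2L, 3L), p_die = p_die_chd, to = 3L,
                           cost = co$chd_cost_subsequent, u = u$u_chd_subsequent),
                      list(from = c(4L, 5L), p_die = p_die_stroke, to = 5L,
                           cost = co$stroke_cost_subsequent, u = u$u_stroke_subsequent))) {
      idx <- which(state %in% spec$from)
      if (!length(idx)) next
      die <- runif(length(idx)) < spec$p_die
      new_state[idx] <- ifelse(die, 6L, spec$to)
      surv <- idx[!die]
      cost[surv] <- cost[surv] + dc[t] * spec$cost
      qaly[surv] <- qaly[surv] + de[t] * spec$u
      ly[surv] <- ly[surv] + de[t]
    }
    state <- new_state
    if (!any(state != 6L)) break
  }
  totals <- cbind(cost = cost, qaly = qaly, ly = ly)
  list(
    mean = colMeans(totals),
    mc_se = apply(totals, 2, stats::sd) / sqrt(n),
    n = n, totals = totals
  )
}
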