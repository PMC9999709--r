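# Four-state cohort model (event-free, CHD, stroke, dead) with first-year
# tunnel sub-states, run over annual cycles. All transitions and rewards
# occur at cycle end; no half-cycle correction. Survivors of a first event
# remain in the corresponding event state until death (no second events,
# no cross-event transitions).

#' Per-cycle transition probabilities at one age
#'
#' From the event-free state, CHD event, stroke event and non-CVD death
#' compete as a mutually exclusive multinomial (their probabilities must
#' sum to at most 1; the remainder stays event-free). Baseline event
#' probabilities are multiplied by the arm's effective relative risks.
#' Occupants of the post-event states face the cause-specific annual
#' fatality combined independently with net background mortality,
#' `1 - (1 - p_fatal)(1 - q_bg)`.
#'
#' @param age current age in years
#' @param params an `irapen_params` object
#' @param rr_chd,rr_stroke effective relative risks for the arm
#' @return an `irapen_transitions` list: `p_chd_event`, `p_stroke_event`,
#'   `p_other_death`, `chd_fatal`, `chd_fatal_prehospital_fraction`,
#'   `stroke_fatal`, `p_death_from_chd`, `p_death_from_stroke`
#' @export
build_cycle_transitions <- function(age, params, rr_chd, rr_stroke) {
  if (rr_chd < 0 || rr_stroke < 0) .stopf("relative risks must be >= 0")
  base <- baseline_event_probs(params, age)
  lt <- params$mortality$background_life_table
  i <- match(age, lt$age)
  if (is.na(i)) .stopf("age %s not covered by the background life table", age)
  q_bg <- lt$qx[i]
  p_chd <- base[["chd"]] * rr_chd
  p_stroke <- base[["stroke"]] * rr_stroke
  if (p_chd + p_stroke + q_bg > 1) {
    .stopf("transition probabilities sum to > 1 at age %s", age)
  }
  m <- params$mortality
  structure(list(
    age = age,
    p_chd_event = p_chd, p_stroke_event = p_stroke, p_other_death = q_bg,
    chd_fatal = m$chd_case_fatality_year1,
    chd_fatal_prehospital_fraction = params$costs$prehospital_chd_death_fraction,
    stroke_fatal = m$stroke_case_fatality_year1,
    p_death_from_chd = 1 - (1 - m$post_chd_annual_fatality) * (1 - q_bg),
    p_death_from_stroke = 1 - (1 - m$post_stroke_annual_fatality) * (1 - q_bg)
  ), class = "irapen_transitions")
}

.arm_rrs <- function(params, arm) {
  if (arm == "status_quo") return(c(chd = 1, stroke = 1))
  pkg <- build_package(params$profile$cohort_label, params$profile$diabetic,
                       treatments = params$treatments)
  adh <- params$economics$adherence
  c(chd = effective_rr(pkg, "chd", adh), stroke = effective_rr(pkg, "stroke", adh))
}

#' Run the cohort through the Markov model
#'
#' Advances state occupancy from 100% event-free at cycle 0 through
#' `horizon_cycles` annual cycles. Event entrants split into first-year
#' fatalities (moved to dead, with prehospital/hospital CHD accounting
#' and early-stroke accounting) and survivors, who occupy the first-year
#' tunnel state for exactly one cycle before moving to the chronic
#' post-event state or dying.
#'
#' @param params a validated `irapen_params` object
#' @param arm `"status_quo"` (no prevention) or `"irapen"`
#' @return an `irapen_trace`: a data.frame with one row per cycle
#'   (0..horizon), state-occupancy columns, and per-cycle cause-of-death
#'   accounting columns (`fatal_chd_prehospital`, `fatal_chd_hospital`,
#'   `fatal_stroke_early`, `other_death` — flows into dead during that
#'   cycle)
#' @export
run_cohort <- function(params, arm = c("status_quo", "irapen")) {
  arm <- match.arg(arm)
  H <- params$economics$horizon_cycles
  rr <- .arm_rrs(params, arm)
  cols <- c(ALL_STATES, "fatal_chd_prehospital", "fatal_chd_hospital",
            "fatal_stroke_early", "other_death")
  tr <- matrix(0, nrow = H + 1L, ncol = length(cols),
               dimnames = list(NULL, cols))
  tr[1L, "event_free"] <- 1
  s <- tr[1L, ALL_STATES]
  for (t in seq_len(H)) {
    age <- params$profile$age_entry + t - 1L
    ct <- build_cycle_transitions(age, params, rr[["chd"]], rr[["stroke"]])
    ef <- s[["event_free"]]
    new_chd <- ef * ct$p_chd_event
    new_stroke <- ef * ct$p_stroke_event
    ef_death <- ef * ct$p_other_death
    chd_fatal <- new_chd * ct$chd_fatal
    stroke_fatal <- new_stroke * ct$stroke_fatal
    # first-year tunnel occupants and chronic occupants face year-2+
    # mortality when leaving their state at the end of this cycle
    chd_pool <- s[["chd_year1"]] + s[["chd_post"]]
    stroke_pool <- s[["stroke_year1"]] + s[["stroke_post"]]
    chd_pool_death <- chd_pool * ct$p_death_from_chd
    stroke_pool_death <- stroke_pool * ct$p_death_from_stroke

    s_next <- c(
      event_free = ef - new_chd - new_stroke - ef_death,
      chd_year1 = new_chd - chd_fatal,
      chd_post = chd_pool - chd_pool_death,
      stroke_year1 = new_stroke - stroke_fatal,
      stroke_post = stroke_pool - stroke_pool_death,
      dead = s[["dead"]] + ef_death + chd_fatal + stroke_fatal +
        chd_pool_death + stroke_pool_death
    )
    tr[t + 1L, ALL_STATES] <- s_next
    tr[t + 1L, "fatal_chd_prehospital"] <- chd_fatal * ct$chd_fatal_prehospital_fraction
    tr[t + 1L, "fatal_chd_hospital"] <- chd_fatal * (1 - ct$chd_fatal_prehospital_fraction)
    tr[t + 1L, "fatal_stroke_early"] <- stroke_fatal
    tr[t + 1L, "other_death"] <- ef_death + chd_pool_death + stroke_pool_death
    s <- s_next
  }
  out <- data.frame(cycle = 0:H, tr, check.names = FALSE)
  class(out) <- c("irapen_trace", "data.frame")
  attr(out, "arm") <- arm
  out
}

#' Accumulate discounted costs, QALYs and life years over a trace
#'
#' Rewards are evaluated on end-of-cycle occupancy for cycles 1..horizon,
#' each discounted by `(1+r)^-t` (cycle 0 accrues nothing). Utility 1 for
#' event-free, published first-year/chronic utilities for the event
#' states, 0 when dead. Costs: the program cost applies to event-free
#' occupants in the intervention arm only (event-free under the status
#' quo is costless); event states accrue their first-year or subsequent
#' annual cost; dying costs nothing except that fatal CHD entrants accrue
#' the full first-year CHD cost for the in-hospital fraction (prehospital
#' deaths are costless) and fatal stroke entrants accrue the configured
#' fraction (default 40%) of the first-year stroke cost. Fatal entrants
#' accrue no QALY or LY in their event cycle.
#'
#' @param trace an `irapen_trace` from [run_cohort()]
#' @param params the same parameter set the trace was produced with
#' @param arm arm the trace belongs to (defaults to the trace's own tag)
#' @return a list: `cost`, `qaly`, `ly` (discounted), plus
#'   `qaly_undiscounted`, `ly_undiscounted`, `cost_undiscounted`, and the
#'   per-cycle contribution vectors
#' @export
accumulate_outcomes <- function(trace, params, arm = attr(trace, "arm")) {
  if (is.null(arm)) .stopf("arm not supplied and trace carries no arm tag")
  H <- params$economics$horizon_cycles
  if (nrow(trace) != H + 1L) .stopf("trace and params horizon mismatch")
  co <- params$costs
  u <- params$utilities
  t_idx <- seq_len(H)
  rows <- t_idx + 1L
  program_cost <- if (arm == "irapen") co$program_annual_cost else co$status_quo_eventfree_cost

  cost_t <- program_cost * trace$event_free[rows] +
    co$chd_cost_year1 * trace$chd_year1[rows] +
    co$chd_cost_subsequent * trace$chd_post[rows] +
    co$stroke_cost_year1 * trace$stroke_year1[rows] +
    co$stroke_cost_subsequent * trace$stroke_post[rows] +
    co$chd_cost_year1 * trace$fatal_chd_hospital[rows] +
    co$fatal_stroke_cost_fraction * co$stroke_cost_year1 * trace$fatal_stroke_early[rows] +
    co$death_cost * (trace$fatal_chd_prehospital[rows] + trace$fatal_chd_hospital[rows] +
                       trace$fatal_stroke_early[rows] + trace$other_death[rows])

  qaly_t <- u$u_healthy * trace$event_free[rows] +
    u$u_chd_year1 * trace$chd_year1[rows] +
    u$u_chd_subsequent * trace$chd_post[rows] +
    u$u_stroke_year1 * trace$stroke_year1[rows] +
    u$u_stroke_subsequent * trace$stroke_post[rows]

  ly_t <- rowSums(trace[rows, ALIVE_STATES])

  dc <- (1 + params$economics$discount_rate_costs)^(-t_idx)
  de <- (1 + params$economics$discount_rate_effects)^(-t_idx)
  list(
    cost = sum(cost_t * dc), qaly = sum(qaly_t * de), ly = sum(ly_t * de),
    cost_undiscounted = sum(cost_t),
    qaly_undiscounted = sum(qaly_t), ly_undiscounted = sum(ly_t),
    cost_per_cycle = cost_t, qaly_per_cycle = qaly_t, ly_per_cycle = ly_t
  )
}

#' Run one arm end to end
#'
#' @inheritParams run_cohort
#' @return `accumulate_outcomes()` result with the trace attached as
#'   `$trace`
#' @export
run_arm <- function(params, arm = c("status_quo", "irapen")) {
  arm <- match.arg(arm)
  trace <- run_cohort(params, arm)
  out <- accumulate_outcomes(trace, params, arm)
  out$trace <- trace
  out$arm <- arm
  out
}

#' Export a cohort trace as CSV
#'
#' Deterministic given the parameter set: identical re-runs produce
#' byte-identical files.
#'
#' @param trace an `irapen_trace`
#' @param path output CSV path
#' @export
export_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
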