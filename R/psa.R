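# Probabilistic sensitivity analysis: gamma for costs, beta for
# utilities, lognormal (from the published 95% CI) for component relative
# risks; independent draws, full model run per draw, CE-plane and CEAC
# summaries.

#' Fit a sampling distribution for one uncertain parameter
#'
#' Method-of-moments / CI inversion:
#' * `gamma`: `shape = (mean/SE)^2`, `rate = mean/SE^2` (non-negative
#'   costs);
#' * `beta`: `alpha = mean * (mean(1-mean)/SE^2 - 1)`,
#'   `beta = (1-mean)/mean * alpha` (utilities in `[0,1]`);
#' * `lognormal_from_ci`: `meanlog = log(rr)`,
#'   `sdlog = (log(hi) - log(lo)) / (2 * 1.959964)` (relative risks).
#'
#' A zero SE (or a degenerate CI) yields a point mass at the mean, so a
#' degenerate PSA collapses exactly to the deterministic base case.
#'
#' @param path parameter slash-path the assignment addresses
#' @param family `"gamma"`, `"beta"` or `"lognormal_from_ci"`
#' @param mean,se moments for gamma/beta
#' @param rr,ci_low,ci_high inputs for lognormal CI inversion
#' @return an `irapen_dist` assignment
#' @export
fit_distribution <- function(path, family = c("gamma", "beta", "lognormal_from_ci"),
                             mean = NULL, se = NULL,
                             rr = NULL, ci_low = NULL, ci_high = NULL) {
  family <- match.arg(family)
  hyper <- switch(family,
    gamma = {
      if (mean <= 0) .stopf("%s: gamma needs mean > 0", path)
      if (se < 0) .stopf("%s: negative SE", path)
      if (se == 0) list(point = mean)
      else list(shape = (mean / se)^2, rate = mean / se^2)
    },
    beta = {
      if (!(mean > 0 && mean < 1)) .stopf("%s: beta needs mean in (0,1)", path)
      if (se < 0) .stopf("%s: negative SE", path)
      if (se == 0) list(point = mean)
      else {
        nu <- mean * (1 - mean) / se^2 - 1
        if (nu <= 0) .stopf("%s: beta moment matching infeasible (SE too large)", path)
        list(alpha = mean * nu, beta = (1 - mean) * nu)
      }
    },
    lognormal_from_ci = {
      if (!(ci_low <= rr && rr <= ci_high) || ci_low <= 0) {
        .stopf("%s: need 0 < ci_low <= rr <= ci_high", path)
      }
      if (ci_low == ci_high) list(point = rr)
      else list(meanlog = log(rr), sdlog = (log(ci_high) - log(ci_low)) / (2 * 1.959964))
    }
  )
  structure(list(path = path, family = family, hyper = hyper,
                 mean = mean, se = se, rr = rr),
            class = "irapen_dist")
}

#' Theoretical mean of a fitted assignment
#' @param dist an `irapen_dist`
#' @return the distribution mean (for lognormal, the median `rr` is the
#'   anchored quantity; the mean is `exp(meanlog + sdlog^2/2)`)
#' @export
dist_mean <- function(dist) {
  h <- dist$hyper
  if (!is.null(h$point)) return(h$point)
  switch(dist$family,
    gamma = h$shape / h$rate,
    beta = h$alpha / (h$alpha + h$beta),
    lognormal_from_ci = exp(h$meanlog + h$sdlog^2 / 2)
  )
}

.sample_dist <- function(dist, n) {
  h <- dist$hyper
  if (!is.null(h$point)) return(rep(h$point, n))
  switch(dist$family,
    gamma = rgamma(n, shape = h$shape, rate = h$rate),
    beta = rbeta(n, h$alpha, h$beta),
    lognormal_from_ci = rlnorm(n, h$meanlog, h$sdlog)
  )
}

#' Default PSA distribution assignments for a parameter set
#'
#' Gamma for every cost item (SE from the parameter set, falling back to
#' 0.1 x mean), beta for the four event-state utilities, lognormal from
#' the published 95\% CI for each treatment component's per-outcome
#' relative risk (components are sampled individually, before the overlap
#' combination, so the combined effect varies coherently per draw).
#' Transition baselines (incidences, fatalities, life table) are held
#' fixed.
#'
#' @param params a validated `irapen_params` object
#' @return named list of [fit_distribution()] assignments
#' @export
default_psa_assignments <- function(params) {
  out <- list()
  for (nm in c("program_annual_cost", "chd_cost_year1", "chd_cost_subsequent",
               "stroke_cost_year1", "stroke_cost_subsequent")) {
    mean <- params$costs[[nm]]
    if (mean == 0) next  # a zero cost (screening-only status quo) has no spread
    se <- params$costs$cost_se[[nm]]
    if (is.null(se)) se <- 0.1 * mean
    path <- paste0("costs/", nm)
    out[[path]] <- fit_distribution(path, "gamma", mean = mean, se = se)
  }
  for (nm in c("u_chd_year1", "u_chd_subsequent", "u_stroke_year1", "u_stroke_subsequent")) {
    path <- paste0("utilities/", nm)
    out[[path]] <- fit_distribution(path, "beta", mean = params$utilities[[nm]],
                                    se = params$utilities$se[[nm]])
  }
  pkg <- build_package(params$profile$cohort_label, params$profile$diabetic,
                       treatments = params$treatments)
  for (t in pkg$components) {
    for (oc in c("chd", "stroke")) {
      ci <- t[[paste0("rr_", oc, "_ci")]]
      path <- sprintf("treatments/%s/rr_%s", t$name, oc)
      out[[path]] <- fit_distribution(path, "lognormal_from_ci",
                                      rr = t[[paste0("rr_", oc)]],
                                      ci_low = ci[1], ci_high = ci[2])
    }
  }
  out
}

# cheap per-draw sanity check (full validate_parameters loops the whole
# horizon; here only the structural invariants a draw can break)
.draw_valid <- function(params) {
  co <- params$costs; u <- params$utilities
  if (co$chd_cost_year1 < co$chd_cost_subsequent) return(FALSE)
  if (co$stroke_cost_year1 < co$stroke_cost_subsequent) return(FALSE)
  if (u$u_chd_year1 > u$u_chd_subsequent) return(FALSE)
  if (u$u_stroke_year1 > u$u_stroke_subsequent) return(FALSE)
  TRUE
}

#' Run the probabilistic sensitivity analysis
#'
#' Every assigned parameter is drawn from its distribution via a named
#' RNG substream (one per parameter path, derived from `seed`), so adding
#' an assignment never perturbs the other parameters' draws. Each draw
#' replaces the assigned values, re-runs both arms, and records the CE
#' pair. Draws breaking a type invariant (e.g. a first-year cost drawn
#' below the chronic cost) are redrawn from the parameter's own
#' substream; a redraw rate above 1\% triggers a warning.
#'
#' @param params a validated `irapen_params` object
#' @param n_draws number of Monte-Carlo draws (default 1000)
#' @param seed integer RNG seed
#' @param assignments named list of [fit_distribution()] assignments;
#'   default [default_psa_assignments()]
#' @return an `irapen_psa` list: `samples` (data.frame: draw, per-arm
#'   cost/qaly, `delta_cost`, `delta_qaly`, `cost_effective`,
#'   `cost_saving`), `draws` (matrix of sampled parameter values),
#'   `summary` (fractions cost-effective / cost-saving at the threshold,
#'   mean deltas, redraw count), `seed`, `threshold`
#' @export
run_psa <- function(params, n_draws = 1000, seed = 1,
                    assignments = default_psa_assignments(params)) {
  if (n_draws < 1) .stopf("n_draws must be >= 1")
  paths <- names(assignments)
  draws <- matrix(NA_real_, nrow = n_draws, ncol = length(paths),
                  dimnames = list(NULL, paths))
  for (p in paths) {
    set.seed(.substream_seed(seed, p))
    draws[, p] <- .sample_dist(assignments[[p]], n_draws)
  }
  threshold <- params$economics$wtp_threshold
  n_redraw <- 0L
  res <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    attempt <- 0L
    repeat {
      pi <- params
      for (p in paths) pi <- param_set(pi, p, draws[i, p])
      if (.draw_valid(pi)) break
      attempt <- attempt + 1L
      n_redraw <- n_redraw + 1L
      if (attempt > 100L) .stopf("draw %d: could not produce a valid parameter set", i)
      set.seed(.substream_seed(seed, sprintf("redraw/%d/%d", i, attempt)))
      for (p in paths) draws[i, p] <- .sample_dist(assignments[[p]], 1L)
    }
    ce <- run_cea(pi)
    res[[i]] <- c(cost_sq = ce$arms$status_quo$cost, qaly_sq = ce$arms$status_quo$qaly,
                  cost_ir = ce$arms$irapen$cost, qaly_ir = ce$arms$irapen$qaly,
                  delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
                  nmb = ce$nmb)
  }
  m <- do.call(rbind, res)
  samples <- data.frame(draw = seq_len(n_draws), m)
  samples$cost_saving <- samples$delta_cost < 0 & samples$delta_qaly > 0
  samples$cost_effective <- samples$nmb > 0
  if (n_redraw > 0.01 * n_draws) {
    warning(sprintf("PSA redraw rate %.1f%% exceeds 1%%", 100 * n_redraw / n_draws),
            call. = FALSE)
  }
  structure(list(
    samples = samples, draws = draws,
    summary = list(
      n_draws = n_draws,
      fraction_cost_effective = mean(samples$cost_effective),
      fraction_cost_saving = mean(samples$cost_saving),
      mean_delta_cost = mean(samples$delta_cost),
      mean_delta_qaly = mean(samples$delta_qaly),
      n_redraw = n_redraw
    ),
    seed = seed, threshold = threshold
  ), class = "irapen_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' Probability the intervention is cost-effective (positive net monetary
#' benefit) across a grid of willingness-to-pay thresholds.
#'
#' @param psa an `irapen_psa` from [run_psa()], or its `samples`
#'   data.frame
#' @param thresholds non-empty numeric grid of thresholds (USD/QALY)
#' @return data.frame: `threshold`, `probability_cost_effective`
#' @export
ceac <- function(psa, thresholds) {
  if (length(thresholds) == 0L) .stopf("threshold grid must be non-empty")
  samples <- if (inherits(psa, "irapen_psa")) psa$samples else psa
  if (nrow(samples) == 0L) .stopf("no PSA samples")
  prob <- vapply(thresholds, function(th) {
    mean(th * samples$delta_qaly - samples$delta_cost > 0)
  }, numeric(1))
  data.frame(threshold = thresholds, probability_cost_effective = prob)
}

#' Write CE-plane samples and CEAC to CSV
#'
#' @param psa an `irapen_psa`
#' @param plane_path,ceac_path output CSV paths (`NULL` to skip either)
#' @param thresholds CEAC threshold grid
#' @export
export_psa <- function(psa, plane_path = NULL, ceac_path = NULL,
                       thresholds = seq(0, 10000, by = 250)) {
  if (!is.null(plane_path)) {
    write.csv(psa$samples[, c("draw", "delta_cost", "delta_qaly",
                              "cost_effective", "cost_saving")],
              plane_path, row.names = FALSE)
  }
  if (!is.null(ceac_path)) write.csv(ceac(psa, thresholds), ceac_path, row.names = FALSE)
  invisible(psa)
}
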