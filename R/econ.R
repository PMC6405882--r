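#' Discount factor
#'
#' Costs and effects beyond one year are discounted at a fixed annual rate:
#' the factor is 1 for `t < 1` (the first year is undiscounted) and
#' `(1 + rate)^(-t)` from `t = 1` on, with end-of-cycle accrual.
#'
#' @param t Time in years (cycle index), non-negative.
#' @param rate Annual discount rate (proportion, >= 0; default 0.05).
#' @return Discount factor(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(0:3, 0.05)
discount_factor <- function(t, rate = 0.05) {
  if (rate < 0) stop("discount rate must be non-negative")
  stopifnot(all(t >= 0))
  ifelse(t < 1, 1, (1 + rate)^(-t))
}

#' Utility-weight table (PLACEHOLDER defaults)
#'
#' Health-state utility weights by age band and weight status, used to
#' accumulate quality-adjusted life years. The defaults shipped here are
#' clearly-labelled placeholders (healthy 0.95, overweight 0.93, obese
#' 0.88, underweight 0.92 across the whole 4-16 age range); substantive
#' analyses must supply utilities from an appropriate review of
#' child/adolescent weight-related quality of life.
#'
#' @param age_lo,age_hi Band boundaries, half-open `[lo, hi)`.
#' @param status Weight-status category per row.
#' @param utility Utility weight in \[0, 1\] per row.
#' @return Data frame with one row per (band, status).
#' @export
utility_table <- function(age_lo = rep(4, 4), age_hi = rep(16, 4),
                          status = c("underweight", "healthy", "overweight",
                                     "obese"),
                          utility = c(0.92, 0.95, 0.93, 0.88)) {
  if (any(utility < 0 | utility > 1)) stop("utilities must lie in [0, 1]")
  out <- data.frame(age_lo = age_lo, age_hi = age_hi, status = status,
                    utility = utility, stringsAsFactors = FALSE)
  attr(out, "placeholder") <- TRUE
  out
}

#' Annual cost table (PLACEHOLDER defaults)
#'
#' Annual healthcare costs by age band and weight status: `annual_cost` is
#' the direct (payer-perspective) cost, `indirect_cost` is added under the
#' societal perspective. Defaults are zero placeholders.
#'
#' @inheritParams utility_table
#' @param annual_cost Direct annual cost per row (currency units/year).
#' @param indirect_cost Indirect annual cost per row.
#' @return Data frame with one row per (band, status).
#' @export
cost_table <- function(age_lo = rep(4, 4), age_hi = rep(16, 4),
                       status = c("underweight", "healthy", "overweight",
                                  "obese"),
                       annual_cost = rep(0, 4), indirect_cost = rep(0, 4)) {
  if (any(annual_cost < 0 | indirect_cost < 0)) stop("costs must be >= 0")
  out <- data.frame(age_lo = age_lo, age_hi = age_hi, status = status,
                    annual_cost = annual_cost, indirect_cost = indirect_cost,
                    stringsAsFactors = FALSE)
  attr(out, "placeholder") <- TRUE
  out
}

#' Economic-evaluation configuration
#'
#' @param discount_rate Annual discount rate (default 0.05).
#' @param perspective `"payer"` (direct costs only) or `"societal"`
#'   (direct + indirect).
#' @param horizon Optional number of cycles to include (default: all).
#' @return List of class `econ_config`.
#' @export
econ_config <- function(discount_rate = 0.05,
                        perspective = c("payer", "societal"),
                        horizon = NULL) {
  perspective <- match.arg(perspective)
  stopifnot(discount_rate >= 0)
  structure(list(discount_rate = discount_rate, perspective = perspective,
                 horizon = horizon), class = "econ_config")
}

.band_lookup <- function(table, age, status, value_cols, what) {
  n <- length(age)
  out <- matrix(NA_real_, n, length(value_cols),
                dimnames = list(NULL, value_cols))
  for (j in seq_len(nrow(table))) {
    hit <- age >= table$age_lo[j] & age < table$age_hi[j] &
      status == table$status[j]
    for (vc in value_cols) out[hit, vc] <- table[[vc]][j]
  }
  if (anyNA(out[, 1])) {
    miss <- which(is.na(out[, 1]))[1]
    stop(sprintf("%s table has no row covering (age %s, status %s)", what,
                 age[miss], status[miss]))
  }
  out
}

# Accrual panel: each cycle t represents the year lived from t to t+1, so
# costs and QALYs accrue over cycles 0..H-1; the final snapshot is a point
# in time, not a lived year.
.traj_panel <- function(traj, config) {
  H <- min(config$horizon %||% traj$n_cycles, traj$n_cycles)
  traj$panel[traj$panel$cycle < H, ]
}

#' Accumulate discounted quality-adjusted life years
#'
#' Per individual, sums `alive * utility(age, status) * discount_factor`
#' over cycles; weighted population summaries come from the survey module.
#' Cycles after death contribute exactly zero.
#'
#' @param traj A `trajectory_output` from [run_simulation()].
#' @param utilities A [utility_table()].
#' @param config An [econ_config()].
#' @return List: `per_individual` (data frame `child_id`, `qalys`) and
#'   `estimate` (weighted-mean QALYs, a `svy_estimate`).
#' @export
accumulate_qalys <- function(traj, utilities = utility_table(),
                             config = econ_config()) {
  p <- .traj_panel(traj, config)
  contrib <- numeric(nrow(p))
  ok <- p$alive
  u <- .band_lookup(utilities, p$age[ok], as.character(p$status[ok]),
                    "utility", "utility")[, 1]
  contrib[ok] <- u * discount_factor(p$cycle[ok], config$discount_rate)
  per <- stats::aggregate(contrib, by = list(child_id = p$child_id), FUN = sum)
  names(per)[2] <- "qalys"
  base <- p[p$cycle == 0, ]
  per <- per[match(base$child_id, per$child_id), ]
  est <- svy_mean(per$qalys, base$weight, base$stratum, base$psu)
  list(per_individual = per, estimate = est)
}

#' Accumulate discounted costs
#'
#' Annual (age, status) costs accrue for every alive cycle, discounted;
#' indirect costs are added under the societal perspective; each enrolled
#' child additionally incurs the intervention's per-participant delivery
#' cost at its start cycle, discounted.
#'
#' @param traj A `trajectory_output` (its `enrollments` carry the
#'   intervention costs).
#' @param costs A [cost_table()].
#' @param config An [econ_config()].
#' @return List: `per_individual` (`child_id`, `cost`) and `estimate`
#'   (weighted-mean cost, a `svy_estimate`).
#' @export
accumulate_costs <- function(traj, costs = cost_table(),
                             config = econ_config()) {
  p <- .traj_panel(traj, config)
  contrib <- numeric(nrow(p))
  ok <- p$alive
  cc <- .band_lookup(costs, p$age[ok], as.character(p$status[ok]),
                     c("annual_cost", "indirect_cost"), "cost")
  annual <- cc[, "annual_cost"]
  if (config$perspective == "societal") annual <- annual + cc[, "indirect_cost"]
  contrib[ok] <- annual * discount_factor(p$cycle[ok], config$discount_rate)
  per <- stats::aggregate(contrib, by = list(child_id = p$child_id), FUN = sum)
  names(per)[2] <- "cost"
  en <- traj$enrollments
  if (nrow(en)) {
    extra <- en$cost_per_participant *
      discount_factor(en$start_cycle, config$discount_rate)
    add <- tapply(extra, en$child_id, sum)
    idx <- match(as.integer(names(add)), per$child_id)
    per$cost[idx] <- per$cost[idx] + as.numeric(add)
  }
  base <- p[p$cycle == 0, ]
  per <- per[match(base$child_id, per$child_id), ]
  est <- svy_mean(per$cost, base$weight, base$stratum, base$psu)
  list(per_individual = per, estimate = est)
}

#' Summarize one simulation arm for economic comparison
#'
#' @param traj A `trajectory_output`.
#' @param utilities,costs,config As in [accumulate_qalys()] /
#'   [accumulate_costs()].
#' @return List of class `arm_result`: weighted mean discounted cost and
#'   QALYs, and weighted mean endpoint BMI and z-score (alive individuals
#'   at the final recorded cycle).
#' @export
evaluate_arm <- function(traj, utilities = utility_table(),
                         costs = cost_table(), config = econ_config()) {
  q <- accumulate_qalys(traj, utilities, config)
  cst <- accumulate_costs(traj, costs, config)
  p <- traj$panel
  last <- p[p$cycle == max(p$cycle) & p$alive, ]
  structure(list(
    mean_cost = cst$estimate$point, mean_qalys = q$estimate$point,
    endpoint_mean_bmi = svy_mean(last$bmi, last$weight, last$stratum,
                                 last$psu)$point,
    endpoint_mean_z = svy_mean(last$z, last$weight, last$stratum,
                               last$psu)$point,
    cost = cst, qalys = q), class = "arm_result")
}

#' Incremental cost-effectiveness ratio
#'
#' Compares an intervention arm with a control arm simulated from the same
#' baseline and seed (common random numbers). The effect delta is oriented
#' so health gains are positive: QALYs gained, or BMI (z-score) units
#' *avoided* (control minus intervention). An intervention that is cheaper
#' and more effective is `dominant`; costlier and less effective,
#' `dominated`; zero effect delta gives no ratio (`indeterminate`).
#'
#' @param intervention_arm,control_arm `arm_result`s from [evaluate_arm()].
#' @param metric `"qaly"`, `"bmi"` or `"bmi_z"`.
#' @return List of class `icer_result`: `delta_cost`, `delta_effect`,
#'   `ratio` (or `NA`), `dominance`, `metric`.
#' @export
#' @examples
#' a <- structure(list(mean_cost = 2000, mean_qalys = 11,
#'   endpoint_mean_bmi = 0, endpoint_mean_z = 0), class = "arm_result")
#' b <- structure(list(mean_cost = 1000, mean_qalys = 10,
#'   endpoint_mean_bmi = 0, endpoint_mean_z = 0), class = "arm_result")
#' compute_icer(a, b)$ratio # 1000 per QALY
compute_icer <- function(intervention_arm, control_arm,
                         metric = c("qaly", "bmi", "bmi_z")) {
  metric <- match.arg(metric)
  dc <- intervention_arm$mean_cost - control_arm$mean_cost
  de <- switch(metric,
               qaly = intervention_arm$mean_qalys - control_arm$mean_qalys,
               bmi = control_arm$endpoint_mean_bmi -
                 intervention_arm$endpoint_mean_bmi,
               bmi_z = control_arm$endpoint_mean_z -
                 intervention_arm$endpoint_mean_z)
  dominance <- if (de == 0) "indeterminate"
  else if (dc < 0 && de > 0) "dominant"
  else if (dc > 0 && de < 0) "dominated"
  else "none"
  ratio <- if (de != 0 && dominance == "none") dc / de else NA_real_
  structure(list(delta_cost = dc, delta_effect = de, ratio = ratio,
                 dominance = dominance, metric = metric),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("ICER (%s): delta cost %.4g, delta effect %.4g", x$metric,
              x$delta_cost, x$delta_effect))
  if (!is.na(x$ratio)) cat(sprintf(", ratio %.4g per unit", x$ratio))
  if (x$dominance != "none") cat(" [", x$dominance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Run a paired control/intervention simulation with common random numbers
#'
#' Both arms are simulated from the same baseline cohort and seed, so that
#' their difference reflects only the intervention overlay.
#'
#' @param baseline Baseline cross-section (see [run_simulation()]).
#' @param equations Growth equations.
#' @param intervention An [intervention_spec()] (or list of them).
#' @param lifetable Life table or `NULL`.
#' @param engine An [engine_config()].
#' @param utilities,costs,econ Economic inputs.
#' @param metric ICER metric, see [compute_icer()].
#' @return List: `control`, `intervention` (`arm_result`s) and `icer`.
#' @export
run_paired_arms <- function(baseline, equations, intervention,
                            lifetable = NULL, engine = engine_config(),
                            utilities = utility_table(), costs = cost_table(),
                            econ = econ_config(), metric = "qaly") {
  ctrl <- run_simulation(baseline, equations, lifetable, list(), engine)
  arm <- run_simulation(baseline, equations, lifetable, intervention, engine)
  ac <- evaluate_arm(ctrl, utilities, costs, econ)
  ai <- evaluate_arm(arm, utilities, costs, econ)
  list(control = ac, intervention = ai,
       icer = compute_icer(ai, ac, metric))
}

#' One-at-a-time sensitivity scan over economic and effect parameters
#'
#' Re-runs the paired simulation (same seeds) for the base case and for
#' each supplied bound of the intervention effect size, effect duration and
#' discount rate, emitting one ICER row per scenario.
#'
#' @inheritParams run_paired_arms
#' @param effect_range,duration_range,discount_range Numeric vectors of
#'   alternative values to scan (may be empty).
#' @return Data frame: scenario label, parameter value, delta cost, delta
#'   effect, ratio, dominance.
#' @export
sensitivity_scan <- function(baseline, equations, intervention,
                             lifetable = NULL, engine = engine_config(),
                             utilities = utility_table(), costs = cost_table(),
                             econ = econ_config(), metric = "qaly",
                             effect_range = numeric(),
                             duration_range = numeric(),
                             discount_range = numeric()) {
  scenarios <- list(list(label = "base", spec = intervention, econ = econ))
  for (e in effect_range) {
    sp <- intervention; sp$effect <- e
    scenarios[[length(scenarios) + 1]] <-
      list(label = sprintf("effect=%g", e), spec = sp, econ = econ)
  }
  for (d in duration_range) {
    sp <- intervention; sp$duration <- d
    scenarios[[length(scenarios) + 1]] <-
      list(label = sprintf("duration=%g", d), spec = sp, econ = econ)
  }
  for (r in discount_range) {
    ec <- econ; ec$discount_rate <- r
    scenarios[[length(scenarios) + 1]] <-
      list(label = sprintf("discount=%g", r), spec = intervention, econ = ec)
  }
  rows <- lapply(scenarios, function(sc) {
    res <- run_paired_arms(baseline, equations, sc$spec, lifetable, engine,
                           utilities, costs, sc$econ, metric)
    data.frame(scenario = sc$label, delta_cost = res$icer$delta_cost,
               delta_effect = res$icer$delta_effect, ratio = res$icer$ratio,
               dominance = res$icer$dominance, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
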