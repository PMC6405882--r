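#' Life tables
#'
#' A life table gives the annual probability of death `q` by sex and single
#' year of age. `read_life_table()` reads a delimited text file with columns
#' `sex`, `age_years`, `q`; `default_life_table()` returns the bundled
#' *synthetic* table with realistic (order 1e-4) child mortality;
#' `zero_life_table()` returns `q = 0` everywhere, the configuration under
#' which the simulated population is exactly conserved.
#'
#' @param path File path.
#' @return Data frame with columns `sex`, `age_years`, `q`.
#' @name life_tables
NULL

#' @rdname life_tables
#' @export
read_life_table <- function(path) {
  lt <- utils::read.delim(path, comment.char = "#", sep = "",
                          stringsAsFactors = FALSE)
  if (!all(c("sex", "age_years", "q") %in% names(lt)))
    stop("life table must have columns sex, age_years, q")
  if (any(lt$q < 0 | lt$q > 1)) stop("life table q must lie in [0, 1]")
  lt
}

#' @rdname life_tables
#' @export
default_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_synthetic.tsv",
                              package = "bmisim"))
}

#' @rdname life_tables
#' @param ages Ages covered.
#' @export
zero_life_table <- function(ages = 4:15) {
  expand.grid(sex = c("M", "F"), age_years = ages, q = 0,
              stringsAsFactors = FALSE)[, c("sex", "age_years", "q")]
}

.q_lookup <- function(lifetable, sex, age) {
  key <- paste(lifetable$sex, lifetable$age_years)
  idx <- match(paste(sex, age), key)
  if (anyNA(idx))
    stop("life table missing row(s) for: ",
         paste(unique(paste(sex, age)[is.na(idx)]), collapse = ", "))
  lifetable$q[idx]
}

#' Specify an intervention overlay
#'
#' An intervention reduces the expected annual BMI gain of enrolled children
#' by `effect` (kg/m^2 per year) for `duration` years, optionally decaying
#' over that window. Eligibility (age window, and optionally weight status)
#' is evaluated once, at `start_cycle`; the effect then applies to the
#' transitions starting at cycles `start_cycle, ..., start_cycle +
#' duration - 1` and is zero afterwards (the conservative assumption that
#' effects persist only for the duration of the intervention).
#'
#' @param name Label.
#' @param eligible_age_lo,eligible_age_hi Inclusive age window (years)
#'   within \[4, 16).
#' @param eligible_statuses Optional character vector of weight-status
#'   categories (see [classify_status()]); `NULL` = all.
#' @param effect Reduction in expected annual BMI gain, kg/m^2 per year
#'   (non-negative).
#' @param duration Years the effect lasts (>= 1).
#' @param decay `"none"`, `"linear"` (to zero at `duration`), or
#'   `"exponential"` with the given `half_life` in years.
#' @param half_life Half-life for exponential decay.
#' @param cost_per_participant One-off delivery cost per enrolled child.
#' @param start_cycle Cycle index at which enrollment happens.
#' @return A list of class `intervention_spec`.
#' @export
intervention_spec <- function(name = "intervention", eligible_age_lo = 4,
                              eligible_age_hi = 15, eligible_statuses = NULL,
                              effect = 0, duration = 1,
                              decay = c("none", "linear", "exponential"),
                              half_life = 1, cost_per_participant = 0,
                              start_cycle = 0) {
  decay <- match.arg(decay)
  stopifnot(effect >= 0, duration >= 1, eligible_age_lo >= 4,
            eligible_age_hi < 16, half_life > 0, start_cycle >= 0)
  structure(list(name = name, eligible_age_lo = eligible_age_lo,
                 eligible_age_hi = eligible_age_hi,
                 eligible_statuses = eligible_statuses, effect = effect,
                 duration = duration, decay = decay, half_life = half_life,
                 cost_per_participant = cost_per_participant,
                 start_cycle = start_cycle),
            class = "intervention_spec")
}

#' Decay-adjusted intervention effect at a given time since enrollment
#'
#' Zero outside `[0, duration)`; within the window: the full `effect` for
#' `decay = "none"`, `effect * (1 - t/duration)` for linear decay, and
#' `effect * 2^(-t/half_life)` for exponential decay.
#'
#' @param spec An [intervention_spec()].
#' @param years_since_start Non-negative time since enrollment (vector).
#' @return Effect now, kg/m^2 per year.
#' @export
apply_intervention_effect <- function(spec, years_since_start) {
  t <- years_since_start
  stopifnot(all(t >= 0))
  inside <- t < spec$duration
  base <- switch(spec$decay,
                 none = rep_len(spec$effect, length(t)),
                 linear = spec$effect * (1 - t / spec$duration),
                 exponential = spec$effect * 2^(-t / spec$half_life),
                 stop("unknown decay kind: ", spec$decay))
  ifelse(inside, base, 0)
}

#' Engine configuration
#'
#' @param n_cycles Number of annual cycles to simulate.
#' @param seed Integer seed for the engine's random draws.
#' @param stochastic_residual Add a residual draw each cycle (truncated
#'   normal, +/- 4 SD); turn off for deterministic expected-change
#'   propagation.
#' @param bmi_floor Lower clamp on BMI, kg/m^2.
#' @param annualize Use observation-interval-consistent annual coefficients
#'   for equation sets fitted on `delta_t > 1` data (see Details of
#'   [run_simulation()]); has no effect when `delta_t = 1`.
#' @return List of class `engine_config`.
#' @export
engine_config <- function(n_cycles = 10, seed = 1L, stochastic_residual = TRUE,
                          bmi_floor = 10, annualize = TRUE) {
  stopifnot(n_cycles >= 0)
  structure(list(n_cycles = as.integer(n_cycles), seed = as.integer(seed),
                 stochastic_residual = stochastic_residual,
                 bmi_floor = bmi_floor, annualize = annualize),
            class = "engine_config")
}

# Per-cycle coefficients consistent with the fitting interval. For an
# equation fitted on changes observed over delta_t years, the annual affine
# map b -> phi*b + c0 + ca*a is the exact delta_t-th root of the fitted
# interval map b -> (1 + dt*beta_bmi)*b + dt*(beta0 + beta_age*a), and the
# per-cycle innovation SD accumulates over delta_t cycles to the observed
# between-wave residual SD (dt * resid_sd at the annualized-rate scale).
.annualized_coefs <- function(eq, annualize) {
  dt <- if (annualize && is.finite(eq$delta_t)) round(eq$delta_t) else 1L
  if (dt <= 1)
    return(list(phi = 1 + eq$beta_bmi, c0 = eq$beta0, ca = eq$beta_age,
                sd_fac = 1))
  root <- 1 + dt * eq$beta_bmi
  if (root <= 0) stop("cannot annualize: 1 + delta_t * beta_bmi <= 0")
  phi <- root^(1 / dt)
  S <- sum(phi^(0:(dt - 1)))
  TT <- sum((0:(dt - 1)) * phi^((dt - 1):0))
  ca <- dt * eq$beta_age / S
  c0 <- (dt * eq$beta0 - ca * TT) / S
  sd_fac <- dt / sqrt(sum(phi^(2 * (0:(dt - 1)))))
  list(phi = phi, c0 = c0, ca = ca, sd_fac = sd_fac)
}

#' Advance the simulation state by one annual cycle
#'
#' Applies, in order, to each alive individual: (1) mortality draw with
#' probability `q(age, sex)`; survivors then (2) receive the expected
#' annual BMI change from their growth-equation segment, (3) reduced by the
#' decay-adjusted effects of any active interventions, (4) plus, if
#' `config$stochastic_residual`, a truncated-normal residual draw whose SD
#' may depend linearly on current BMI; (5) the result is clamped at
#' `config$bmi_floor` and age advances by one year. Dead individuals carry
#' no further updates.
#'
#' @param state Data frame with columns `child_id`, `sex`, `age`, `bmi`,
#'   `alive` (and anything else, carried through).
#' @param equations A `growth_equation_set`.
#' @param lifetable Life table, or `NULL` for no mortality.
#' @param active List of `list(spec =, enrolled =)` entries with enrolled
#'   child ids; effects of overlapping interventions add.
#' @param config [engine_config()].
#' @param cycle Current cycle index (used for intervention timing).
#' @return Updated state.
#' @export
advance_cycle <- function(state, equations, lifetable = NULL, active = list(),
                          config = engine_config(), cycle = 0) {
  al <- which(state$alive)
  if (!length(al)) return(state)
  if (!is.null(lifetable)) {
    q <- .q_lookup(lifetable, state$sex[al], state$age[al])
    dies <- stats::runif(length(al)) < q
    state$alive[al[dies]] <- FALSE
    al <- al[!dies]
  }
  if (length(al)) {
    sex <- state$sex[al]; age <- state$age[al]; bmi <- state$bmi[al]
    j <- .segment_index(equations, sex, age)
    delta <- numeric(length(al))
    sdv <- numeric(length(al))
    for (jj in unique(j)) {
      eq <- equations[jj, ]
      ac <- .annualized_coefs(eq, config$annualize)
      here <- j == jj
      delta[here] <- ac$c0 + ac$ca * age[here] + (ac$phi - 1) * bmi[here]
      sdv[here] <- pmax(eq$resid_sd_intercept + eq$resid_sd_slope * bmi[here],
                        0.01) * ac$sd_fac
    }
    if (length(active)) {
      reduction <- numeric(length(al))
      for (a in active) {
        t_since <- cycle - a$spec$start_cycle
        if (t_since < 0) next
        eff <- apply_intervention_effect(a$spec, t_since)
        reduction <- reduction + eff * (state$child_id[al] %in% a$enrolled)
      }
      delta <- delta - reduction
    }
    if (config$stochastic_residual) {
      eps <- pmin(pmax(stats::rnorm(length(al)), -4), 4) * sdv
      delta <- delta + eps
    }
    state$bmi[al] <- pmax(bmi + delta, config$bmi_floor)
    state$age[al] <- age + 1
  }
  state
}

#' Run the micro-simulation
#'
#' Initializes the individual-level state from a baseline cross-section and
#' applies [advance_cycle()] for `config$n_cycles` annual cycles, recording
#' every individual's age, BMI, BMI-for-age z-score, weight status and
#' survival at every cycle (including cycle 0). Deterministic given
#' `config$seed`.
#'
#' @details
#' When the growth equations were fitted on biennial observations
#' (`delta_t = 2`) and `config$annualize` is `TRUE` (default), per-cycle
#' coefficients are the exact affine square root of the fitted two-year
#' map, and the per-cycle residual SD is scaled so that the dispersion
#' accumulated over two cycles matches the residual dispersion observed
#' between waves. For manually built sets (`delta_t = 1`) the engine is
#' exactly the affine recursion
#' `b <- b + beta0 + beta_age * age + beta_bmi * b` plus residual.
#'
#' Intervention enrollment happens at each spec's `start_cycle`: children
#' alive, inside the eligible age window, and (if given) in an eligible
#' weight-status category are enrolled once; their expected gain is then
#' reduced by the decay-adjusted effect while active.
#'
#' @param baseline Baseline cohort cross-section: data frame with columns
#'   `child_id`, `age_years`, `sex`, `bmi`, `weight`, `stratum`, `psu`
#'   (wave-1 rows of a generated cohort work directly).
#' @param equations A `growth_equation_set`.
#' @param lifetable Life table or `NULL` (no mortality).
#' @param interventions List of [intervention_spec()]s.
#' @param config [engine_config()].
#' @param ref LMS reference for z-score annotation.
#' @return Object of class `trajectory_output`: list with `panel` (long
#'   data frame: one row per child per cycle), `enrollments` (who was
#'   enrolled in what, when, at what cost) and `config`.
#' @export
run_simulation <- function(baseline, equations, lifetable = NULL,
                           interventions = list(), config = engine_config(),
                           ref = lms_reference()) {
  if (inherits(interventions, "intervention_spec"))
    interventions <- list(interventions)
  if (any(baseline$age_years < 4 | baseline$age_years >= 16))
    stop("baseline ages must lie within [4, 16)")
  set.seed(config$seed)
  state <- data.frame(child_id = baseline$child_id, sex = baseline$sex,
                      age = baseline$age_years, bmi = baseline$bmi,
                      alive = TRUE, weight = baseline$weight,
                      stratum = baseline$stratum, psu = baseline$psu,
                      stringsAsFactors = FALSE)
  if (anyNA(state$bmi)) stop("baseline BMI must be observed for every child")
  active <- list()
  enrollments <- list()
  snap <- function(st, cyc) {
    z <- rep(NA_real_, nrow(st))
    ok <- st$alive
    z[ok] <- bmi_zscore(st$bmi[ok], st$age[ok], st$sex[ok], ref)
    data.frame(child_id = st$child_id, cycle = cyc, age = st$age,
               sex = st$sex, bmi = st$bmi, z = z,
               status = classify_status(z), alive = st$alive,
               weight = st$weight, stratum = st$stratum, psu = st$psu,
               stringsAsFactors = FALSE)
  }
  enroll <- function(st, cyc) {
    for (spec in interventions) {
      if (spec$start_cycle != cyc) next
      elig <- st$alive & st$age >= spec$eligible_age_lo &
        st$age <= spec$eligible_age_hi
      if (!is.null(spec$eligible_statuses)) {
        z <- bmi_zscore(st$bmi, st$age, st$sex, ref)
        elig <- elig & as.character(classify_status(z)) %in% spec$eligible_statuses
      }
      ids <- st$child_id[elig]
      active[[length(active) + 1]] <<- list(spec = spec, enrolled = ids)
      if (length(ids))
        enrollments[[length(enrollments) + 1]] <<- data.frame(
          child_id = ids, name = spec$name, start_cycle = cyc,
          cost_per_participant = spec$cost_per_participant,
          stringsAsFactors = FALSE)
    }
  }
  panel <- vector("list", config$n_cycles + 1)
  enroll(state, 0)
  panel[[1]] <- snap(state, 0)
  cyc <- 0
  while (cyc < config$n_cycles) {
    state <- advance_cycle(state, equations, lifetable, active, config, cyc)
    cyc <- cyc + 1
    enroll(state, cyc)
    panel[[cyc + 1]] <- snap(state, cyc)
  }
  out <- list(panel = do.call(rbind, panel),
              enrollments = if (length(enrollments))
                do.call(rbind, enrollments)
              else data.frame(child_id = integer(), name = character(),
                              start_cycle = integer(),
                              cost_per_participant = numeric()),
              config = config, n_cycles = config$n_cycles)
  class(out) <- "trajectory_output"
  out
}

#' Per-cycle survey-weighted summaries of a simulated trajectory panel
#'
#' @param traj A `trajectory_output`.
#' @param cutoffs [status_cutoffs()].
#' @return Data frame: per cycle, the number alive, weighted mean BMI with
#'   SE, and weighted prevalence (percent) of each weight-status category
#'   plus severe obesity.
#' @export
summarize_trajectory <- function(traj, cutoffs = status_cutoffs()) {
  p <- traj$panel
  out <- lapply(sort(unique(p$cycle)), function(cy) {
    d <- p[p$cycle == cy & p$alive, ]
    m <- svy_mean(d$bmi, d$weight, d$stratum, d$psu)
    prev <- function(cat) svy_prevalence(d$status, cat, d$weight, d$stratum, d$psu)$point
    data.frame(cycle = cy, n_alive = nrow(d), mean_bmi = m$point,
               mean_bmi_se = m$se,
               pct_underweight = prev("underweight"),
               pct_healthy = prev("healthy"),
               pct_overweight = prev("overweight"),
               pct_obese = prev("obese"),
               pct_severe_obese = svy_prevalence(
                 d$z > cutoffs[["severe_obese"]], TRUE,
                 d$weight, d$stratum, d$psu)$point)
  })
  do.call(rbind, out)
}

#' @export
print.trajectory_output <- function(x, ...) {
  cat(sprintf("Trajectory panel: %d individuals x %d cycles (%d rows)\n",
              length(unique(x$panel$child_id)), x$n_cycles + 1, nrow(x$panel)))
  if (nrow(x$enrollments))
    cat(sprintf("Interventions: %d enrollments (%s)\n", nrow(x$enrollments),
                paste(unique(x$enrollments$name), collapse = ", ")))
  invisible(x)
}
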