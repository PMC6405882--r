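.cohort_cols <- c("child_id", "wave", "age_years", "sex", "bmi", "weight",
                  "stratum", "psu", "ses_quintile", "present")

#' Write a cohort table to CSV
#'
#' Fixed column order (`child_id, wave, age_years, sex, bmi, weight,
#' stratum, psu, ses_quintile, present`); missing BMI for absent waves is
#' written as an empty field. Round-trips exactly through [read_cohort()].
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  miss <- setdiff(.cohort_cols, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(cohort[, .cohort_cols], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Strict schema validation with row-numbered errors: required columns,
#' positive weights, positive BMI where present, unique (child_id, wave).
#'
#' @param path CSV path, as written by [write_cohort()].
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  miss <- setdiff(.cohort_cols, names(d))
  if (length(miss))
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "))
  d <- d[, .cohort_cols]
  d$present <- as.logical(d$present)
  bad <- which(!is.finite(d$weight) | d$weight <= 0)
  if (length(bad))
    stop("non-positive or missing survey weight at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(d$present & (!is.finite(d$bmi) | d$bmi <= 0))
  if (length(bad))
    stop("present record without positive BMI at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (anyDuplicated(d[, c("child_id", "wave")]))
    stop("(child_id, wave) pairs must be unique")
  if (!all(d$sex %in% c("M", "F")))
    stop("sex must be coded 'M'/'F'")
  d
}

#' Load a JSON configuration file
#'
#' Reads a hierarchical key-value configuration (JSON) and merges it over
#' the package defaults. Recognized blocks: `generator` (arguments of
#' [generator_config()]), `targets` (arguments of [calibration_targets()]),
#' `segmentation`, `engine` (arguments of [engine_config()]), `life_table`
#' (a path, or `"zero"`, or `"default"`), `seed`.
#'
#' @param path JSON file path.
#' @return A validation-pipeline configuration list.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validation_config(
    generator = do.call(generator_config, as.list(cfg$generator %||% list())),
    targets = do.call(calibration_targets, as.list(cfg$targets %||% list())),
    segmentation = if (!is.null(cfg$segmentation))
      lapply(cfg$segmentation, as.numeric) else default_segmentation(),
    engine = do.call(engine_config, as.list(cfg$engine %||% list())),
    life_table = cfg$life_table %||% "zero",
    seed = cfg$seed %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration of the end-to-end validation pipeline
#'
#' @param generator A [generator_config()].
#' @param targets A [calibration_targets()].
#' @param segmentation Per-sex age boundaries for equation fitting.
#' @param engine An [engine_config()]; `n_cycles` is forced to span the
#'   target waves (10 cycles for the default six biennial waves).
#' @param life_table `"zero"`, `"default"`, a path, or a life-table data
#'   frame. Mortality among children this age is of order 1e-4 per year, so
#'   `"zero"` (the default) changes endpoint estimates negligibly while
#'   keeping the holdout comparison exactly population-conserving.
#' @param seed Overrides both generator and engine seeds when given.
#' @return List of class `validation_config`.
#' @export
validation_config <- function(generator = generator_config(),
                              targets = calibration_targets(),
                              segmentation = default_segmentation(),
                              engine = engine_config(),
                              life_table = "zero", seed = NULL) {
  if (!is.null(seed)) {
    generator$seed <- as.integer(seed)
    engine$seed <- as.integer(seed) + 500000L
  }
  engine$n_cycles <- as.integer(2 * (nrow(targets$waves) - 1))
  structure(list(generator = generator, targets = targets,
                 segmentation = segmentation, engine = engine,
                 life_table = life_table), class = "validation_config")
}

.resolve_life_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.null(x) || identical(x, "zero")) return(NULL)
  if (identical(x, "default")) return(default_life_table())
  read_life_table(x)
}

#' Run the end-to-end holdout validation experiment
#'
#' Executes the full pipeline: generate a calibrated baseline and
#' longitudinal cohort; exclude implausible records; build annualized
#' change pairs and fit the growth equations on the longitudinal data;
#' initialize the simulator with the *wave-1 cross-section only* and run
#' one annual cycle per year to the final wave's age; survey-estimate mean
#' BMI and weight-status prevalences at every cycle; and align even cycles
#' with the target waves. Later waves are thus a holdout: they inform the
#' fitted equations but never enter the simulator's state.
#'
#' A wave row passes when the simulated estimate is within
#' `tolerance_se` design-based standard errors of its target.
#'
#' @param config A [validation_config()] (or [load_config()] output).
#' @param tolerance_se Pass tolerance in units of the estimate's SE.
#' @return Object of class `validation_report`: `table` (per-wave targets
#'   vs simulated estimates with CIs and pass flags), `endpoint`
#'   (baseline/final mean, SD, skewness), `equations`, `fit_report`,
#'   `excluded_count`, `trajectory` (the simulated panel), `cohort`
#'   (the generated longitudinal cohort).
#' @export
run_validation <- function(config = validation_config(), tolerance_se = 3) {
  stopifnot(inherits(config, "validation_config"))
  lt <- .resolve_life_table(config$life_table)
  message("stage 1/5: generating calibrated cohort")
  base <- generate_baseline(config$generator, config$targets)
  coh <- generate_longitudinal(base, config$targets, config$generator)
  message("stage 2/5: excluding implausible observations")
  cl <- clean_observations(coh)
  message("stage 3/5: fitting growth equations")
  pairs <- build_change_pairs(cl$cohort)
  fit <- fit_growth_equations(pairs, config$segmentation,
                              excluded_count = cl$excluded_count)
  message("stage 4/5: simulating from the wave-1 cross-section")
  wave1 <- cl$cohort[cl$cohort$wave == 1L, ]
  traj <- run_simulation(wave1, fit$equations, lt, list(), config$engine)
  message("stage 5/5: survey estimation and wave alignment")
  summ <- summarize_trajectory(traj)
  tw <- config$targets$waves
  rows <- lapply(seq_len(nrow(tw)), function(w) {
    cyc <- 2L * (w - 1L)
    s <- summ[summ$cycle == cyc, ]
    p <- traj$panel[traj$panel$cycle == cyc & traj$panel$alive, ]
    ow <- svy_prevalence(p$status, "overweight", p$weight, p$stratum, p$psu)
    ob <- svy_prevalence(p$status, "obese", p$weight, p$stratum, p$psu)
    m <- svy_mean(p$bmi, p$weight, p$stratum, p$psu)
    data.frame(wave = w, cycle = cyc, age_lo = tw$age_lo[w],
               age_hi = tw$age_hi[w], n_alive = s$n_alive,
               target_mean_bmi = tw$mean_bmi[w], sim_mean_bmi = m$point,
               sim_mean_bmi_se = m$se,
               pass_mean = abs(m$point - tw$mean_bmi[w]) <= tolerance_se * m$se,
               target_pct_overweight = tw$pct_overweight[w],
               sim_pct_overweight = ow$point, sim_pct_overweight_se = ow$se,
               pass_overweight = abs(ow$point - tw$pct_overweight[w]) <=
                 tolerance_se * ow$se,
               target_pct_obese = tw$pct_obese[w], sim_pct_obese = ob$point,
               sim_pct_obese_se = ob$se,
               pass_obese = abs(ob$point - tw$pct_obese[w]) <=
                 tolerance_se * ob$se)
  })
  tab <- do.call(rbind, rows)
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  p0 <- traj$panel[traj$panel$cycle == 0, ]
  pT <- traj$panel[traj$panel$cycle == max(traj$panel$cycle) &
                     traj$panel$alive, ]
  endpoint <- data.frame(
    when = c("baseline", "endpoint"),
    mean = c(mean(p0$bmi), mean(pT$bmi)),
    sd = c(stats::sd(p0$bmi), stats::sd(pT$bmi)),
    skewness = c(skew(p0$bmi), skew(pT$bmi)))
  structure(list(table = tab, endpoint = endpoint,
                 equations = fit$equations, fit_report = fit$report,
                 excluded_count = cl$excluded_count, trajectory = traj,
                 cohort = coh),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Holdout validation: simulated vs target wave statistics\n")
  cols <- c("wave", "cycle", "n_alive", "target_mean_bmi", "sim_mean_bmi",
            "pass_mean", "target_pct_overweight", "sim_pct_overweight",
            "pass_overweight", "target_pct_obese", "sim_pct_obese",
            "pass_obese")
  print.data.frame(x$table[, cols], row.names = FALSE, digits = 4)
  cat("\nBMI distribution (baseline vs endpoint):\n")
  print.data.frame(x$endpoint, row.names = FALSE, digits = 4)
  cat(sprintf("\nObservations excluded as implausible: %d\n",
              x$excluded_count))
  invisible(x)
}

#' Plot the simulated mean-BMI trajectory against targets
#'
#' Dashed line with a shaded 95% confidence band for the simulated weighted
#' mean BMI by age; filled circles for the target wave means.
#'
#' @param report A `validation_report`.
#' @param ... Passed to `plot()`.
#' @export
plot_mean_trajectory <- function(report, ...) {
  s <- summarize_trajectory(report$trajectory)
  t0 <- report$table$age_lo[1] + 0.5
  age <- t0 + s$cycle
  lo <- s$mean_bmi - 1.96 * s$mean_bmi_se
  hi <- s$mean_bmi + 1.96 * s$mean_bmi_se
  graphics::plot(age, s$mean_bmi, type = "n", xlab = "age (years)",
                 ylab = "mean BMI (kg/m^2)", ylim = range(lo, hi,
                 report$table$target_mean_bmi), ...)
  graphics::polygon(c(age, rev(age)), c(lo, rev(hi)), border = NA,
                    col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(age, s$mean_bmi, lty = 2)
  graphics::points(t0 + report$table$cycle, report$table$target_mean_bmi,
                   pch = 16)
  invisible(s)
}

#' Overlay baseline and endpoint BMI densities
#'
#' Mirrors the distribution-change check: kernel densities of the simulated
#' baseline and endpoint BMI cross-sections, plus the generated endpoint
#' wave as the "actual" comparator.
#'
#' @param report A `validation_report`.
#' @param ... Passed to `plot()`.
#' @export
plot_density_overlay <- function(report, ...) {
  p <- report$trajectory$panel
  b <- p$bmi[p$cycle == 0]
  e <- p$bmi[p$cycle == max(p$cycle) & p$alive]
  coh <- report$cohort
  actual <- coh$bmi[coh$wave == max(coh$wave) & !is.na(coh$bmi)]
  db <- stats::density(b); de <- stats::density(e); da <- stats::density(actual)
  graphics::plot(db, col = "blue", xlim = range(db$x, de$x, da$x),
                 ylim = range(db$y, de$y, da$y), main = "",
                 xlab = "BMI (kg/m^2)", ...)
  graphics::lines(da, col = "red")
  graphics::lines(de, lty = 2)
  graphics::legend("topright", lty = c(1, 1, 2),
                   col = c("blue", "red", "black"),
                   legend = c("baseline", "actual endpoint",
                              "simulated endpoint"), bty = "n")
  invisible(NULL)
}
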