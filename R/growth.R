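#' Remove observations with implausible BMI-for-age z-scores
#'
#' Drops cohort rows whose BMI-for-age z-score is strictly greater than
#' `z_limit` or strictly less than `-z_limit` (strict inequalities: a record
#' exactly at the limit is retained). Rows without an observed BMI (absent
#' waves) are kept unchanged. Idempotent.
#'
#' @param cohort Cohort data frame (see [generate_baseline()] for schema).
#' @param ref LMS reference, [lms_reference()].
#' @param z_limit Exclusion threshold in SD units (default 5).
#' @return List with `cohort` (filtered) and `excluded_count`.
#' @export
clean_observations <- function(cohort, ref = lms_reference(), z_limit = 5) {
  obs <- !is.na(cohort$bmi)
  z <- rep(NA_real_, nrow(cohort))
  z[obs] <- bmi_zscore(cohort$bmi[obs], cohort$age_years[obs],
                       cohort$sex[obs], ref)
  drop <- obs & (z > z_limit | z < -z_limit)
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(cohort = out, excluded_count = sum(drop))
}

#' Build annualized BMI-change pairs from a longitudinal cohort
#'
#' For each child and each *consecutive* pair of waves in which both BMIs
#' are observed, computes the annualized change
#' `annual_delta_bmi = (bmi1 - bmi0) / (age1 - age0)` with the exposure age,
#' starting BMI and survey weight attached. Children observed in a single
#' wave, or with a missing intermediate wave, contribute no pair across the
#' gap.
#'
#' @param cohort (Cleaned) longitudinal cohort data frame.
#' @return Data frame of class `change_pairs` with columns `child_id`,
#'   `sex`, `age0`, `bmi0`, `delta_t`, `annual_delta_bmi`, `weight`.
#' @export
build_change_pairs <- function(cohort) {
  keep <- !is.na(cohort$bmi)
  d <- cohort[keep, c("child_id", "wave", "age_years", "sex", "bmi", "weight")]
  d <- d[order(d$child_id, d$wave), ]
  same <- d$child_id[-1] == d$child_id[-nrow(d)]
  adjacent <- d$wave[-1] == d$wave[-nrow(d)] + 1L
  i0 <- which(same & adjacent)
  i1 <- i0 + 1L
  dt <- d$age_years[i1] - d$age_years[i0]
  if (any(dt <= 0))
    stop("non-increasing ages within child(ren) ",
         paste(unique(d$child_id[i0][dt <= 0]), collapse = ", "))
  out <- data.frame(child_id = d$child_id[i0], sex = d$sex[i0],
                    age0 = d$age_years[i0], bmi0 = d$bmi[i0], delta_t = dt,
                    annual_delta_bmi = (d$bmi[i1] - d$bmi[i0]) / dt,
                    weight = d$weight[i0], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("change_pairs", "data.frame")
  out
}

#' Default age segmentation of the growth equations
#'
#' Two age segments for boys and three for girls tiling ages 4 (inclusive)
#' to 16 (exclusive); the extra girls' segment reflects earlier and more
#' variable pubertal timing. Boundaries are half-open `[lo, hi)`.
#'
#' @return Named list of numeric boundary vectors, one per sex.
#' @export
default_segmentation <- function() {
  list(M = c(4, 10, 16), F = c(4, 8, 12, 16))
}

#' Fit sex-stratified piecewise-linear annual BMI-change equations
#'
#' Within each sex-by-age segment, fits weighted least squares of the
#' annualized BMI change on an intercept, exposure age and current BMI:
#' \deqn{\Delta \mathrm{BMI} = \beta_0 + \beta_{age}\,a + \beta_{bmi}\,b + \varepsilon.}
#' The residual scale is estimated both as a constant (weighted residual SD)
#' and, when `bmi_dependent_sd = TRUE`, as a linear function of current BMI
#' (from a weighted regression of absolute residuals, scaled by
#' `sqrt(pi/2)`); the BMI-dependent form is what lets the simulator
#' reproduce the emerging right skew of the BMI distribution.
#'
#' The mean observation interval `delta_t` of the pairs is stored with each
#' equation so that the simulation engine can annualize biennial fits
#' consistently (see [run_simulation()]).
#'
#' @param pairs A `change_pairs` data frame from [build_change_pairs()].
#' @param segmentation Per-sex age boundaries, [default_segmentation()].
#' @param bmi_dependent_sd Model the residual SD as linear in current BMI.
#' @param min_pairs_per_coef Minimum pairs per estimated coefficient
#'   required in every segment (default 10).
#' @return List with `equations` (a `growth_equation_set`) and `report`
#'   (per-equation sample sizes, estimates with standard errors, residual
#'   SDs and the excluded-record count carried from cleaning).
#' @param excluded_count Excluded-observation count to carry into the report.
#' @export
fit_growth_equations <- function(pairs, segmentation = default_segmentation(),
                                 bmi_dependent_sd = TRUE,
                                 min_pairs_per_coef = 10,
                                 excluded_count = 0) {
  rows <- list(); rep_rows <- list()
  for (sx in names(segmentation)) {
    b <- segmentation[[sx]]
    if (b[1] != 4 || b[length(b)] != 16 || is.unsorted(b, strictly = TRUE))
      stop("segmentation for sex ", sx, " must tile [4, 16) with increasing boundaries")
    for (k in seq_len(length(b) - 1)) {
      sub <- pairs[pairs$sex == sx & pairs$age0 >= b[k] & pairs$age0 < b[k + 1], ]
      if (nrow(sub) < 3 * min_pairs_per_coef)
        stop(sprintf("segment %s [%g, %g) has %d pairs; need at least %d",
                     sx, b[k], b[k + 1], nrow(sub), 3 * min_pairs_per_coef))
      fit <- stats::lm(annual_delta_bmi ~ age0 + bmi0, data = sub,
                       weights = sub$weight)
      r <- stats::resid(fit)
      wts <- sub$weight
      resid_sd <- sqrt(sum(wts * r^2) / sum(wts))
      g0 <- resid_sd; g1 <- 0
      if (bmi_dependent_sd && nrow(sub) > 10) {
        sf <- stats::lm(abs(r) ~ bmi0, data = sub, weights = wts)
        g0 <- unname(stats::coef(sf)[1]) * sqrt(pi / 2)
        g1 <- unname(stats::coef(sf)[2]) * sqrt(pi / 2)
      }
      cf <- unname(stats::coef(fit))
      se <- unname(sqrt(diag(stats::vcov(fit))))
      rows[[paste(sx, k)]] <- data.frame(
        sex = sx, age_lo = b[k], age_hi = b[k + 1], beta0 = cf[1],
        beta_age = cf[2], beta_bmi = cf[3], resid_sd = resid_sd,
        resid_sd_intercept = g0, resid_sd_slope = g1,
        delta_t = stats::weighted.mean(sub$delta_t, wts), n_pairs = nrow(sub),
        stringsAsFactors = FALSE)
      rep_rows[[paste(sx, k)]] <- data.frame(
        sex = sx, age_lo = b[k], age_hi = b[k + 1], n_pairs = nrow(sub),
        beta0 = cf[1], se_beta0 = se[1], beta_age = cf[2], se_beta_age = se[2],
        beta_bmi = cf[3], se_beta_bmi = se[3], resid_sd = resid_sd,
        stringsAsFactors = FALSE)
    }
  }
  eqs <- do.call(rbind, rows)
  eqs <- eqs[order(eqs$sex, eqs$age_lo), ]
  rownames(eqs) <- NULL
  class(eqs) <- c("growth_equation_set", "data.frame")
  report <- structure(list(equations = do.call(rbind, rep_rows),
                           n_pairs_total = nrow(pairs),
                           excluded_count = excluded_count),
                      class = "fit_report")
  list(equations = eqs, report = report)
}

#' Construct a growth-equation set directly from coefficients
#'
#' Mainly for engine verification and scenario analysis: builds a
#' `growth_equation_set` from explicit coefficients rather than a fit.
#' `delta_t = 1` means the coefficients are already per annual cycle and the
#' engine applies them literally.
#'
#' @param sex,age_lo,age_hi,beta0,beta_age,beta_bmi Vectors, one entry per
#'   equation segment.
#' @param resid_sd Residual SD per segment (constant form).
#' @param resid_sd_slope Per-unit-BMI slope of the residual SD.
#' @param delta_t Observation interval (years) the coefficients refer to.
#' @return A `growth_equation_set`.
#' @export
growth_equation_set <- function(sex, age_lo, age_hi, beta0, beta_age, beta_bmi,
                                resid_sd = 0, resid_sd_slope = 0, delta_t = 1) {
  eqs <- data.frame(sex = sex, age_lo = age_lo, age_hi = age_hi,
                    beta0 = beta0, beta_age = beta_age, beta_bmi = beta_bmi,
                    resid_sd = resid_sd, resid_sd_intercept = resid_sd,
                    resid_sd_slope = resid_sd_slope, delta_t = delta_t,
                    n_pairs = NA_integer_, stringsAsFactors = FALSE)
  eqs <- eqs[order(eqs$sex, eqs$age_lo), ]
  rownames(eqs) <- NULL
  class(eqs) <- c("growth_equation_set", "data.frame")
  eqs
}

# index of the unique segment containing each (sex, age); errors outside [4,16)
.segment_index <- function(equations, sex, age) {
  if (any(age < 4 | age >= 16))
    stop("age outside [4, 16): no growth equation applies (no extrapolation)")
  idx <- integer(length(age))
  for (j in seq_len(nrow(equations))) {
    hit <- sex == equations$sex[j] & age >= equations$age_lo[j] &
      age < equations$age_hi[j]
    idx[hit] <- j
  }
  if (any(idx == 0))
    stop("no equation segment covers (sex, age) = (",
         paste(unique(paste(sex[idx == 0], age[idx == 0])), collapse = "; "), ")")
  idx
}

#' Expected annual BMI change
#'
#' Evaluates `beta0 + beta_age * age + beta_bmi * bmi` from the unique
#' equation segment containing (`sex`, `age`). Segment boundaries are
#' half-open, so an age exactly at a boundary uses the older segment.
#'
#' @param equations A `growth_equation_set`.
#' @param sex,age,bmi Vectors (recycled to common length).
#' @return Expected BMI change, kg/m^2 per year.
#' @export
#' @examples
#' eqs <- growth_equation_set("M", 4, 16, 2.0, -0.05, -0.04)
#' predict_annual_change(eqs, "M", 5, 16) # 2.0 - 0.25 - 0.64
predict_annual_change <- function(equations, sex, age, bmi) {
  n <- max(length(sex), length(age), length(bmi))
  sex <- rep_len(sex, n); age <- rep_len(age, n); bmi <- rep_len(bmi, n)
  j <- .segment_index(equations, sex, age)
  equations$beta0[j] + equations$beta_age[j] * age + equations$beta_bmi[j] * bmi
}

#' @export
print.growth_equation_set <- function(x, ...) {
  cat("Growth equation set (annualized BMI change, kg/m^2 per year)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Growth-equation fit report\n")
  cat(sprintf("  pairs used: %d   observations excluded upstream: %d\n",
              x$n_pairs_total, x$excluded_count))
  print.data.frame(x$equations, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a growth-equation set to delimited text
#'
#' @param equations A `growth_equation_set`.
#' @param path Output file path (TSV).
#' @export
write_equations <- function(equations, path) {
  utils::write.table(as.data.frame(equations), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a growth-equation set written by [write_equations()]
#'
#' @param path File path.
#' @return A `growth_equation_set`.
#' @export
read_equations <- function(path) {
  eqs <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_lo", "age_hi", "beta0", "beta_age", "beta_bmi",
            "resid_sd", "resid_sd_intercept", "resid_sd_slope", "delta_t")
  if (!all(need %in% names(eqs)))
    stop("equation file missing columns: ",
         paste(setdiff(need, names(eqs)), collapse = ", "))
  class(eqs) <- c("growth_equation_set", "data.frame")
  eqs
}
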