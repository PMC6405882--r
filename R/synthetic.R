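#' Calibration targets for the synthetic cohort generator
#'
#' The wave-level summary statistics the generator reproduces: for each
#' biennial wave, the age pair, the (survey-weighted) mean BMI and the
#' prevalence of overweight and obesity as disjoint reported categories.
#' Defaults are the published child-cohort series used throughout the
#' package's validation pipeline: six waves from ages 4/5 to 14/15, mean BMI
#' rising from 16.3 to 22.2 kg/m^2, representing a weighted population of
#' over 250,000 children.
#'
#' @param age_lo Integer vector: younger age of each wave's age pair.
#' @param mean_bmi Wave mean BMI, kg/m^2.
#' @param pct_overweight,pct_obese Wave prevalences in percent (overweight
#'   excluding obese).
#' @param population_total Weighted number of children represented.
#' @return A list of class `calibration_targets` with a `waves` data frame.
#' @export
calibration_targets <- function(age_lo = seq(4L, 14L, by = 2L),
                                mean_bmi = c(16.3, 16.6, 17.7, 19.2, 20.6, 22.2),
                                pct_overweight = c(23.8, 19.9, 21.9, 22.9, 21.9, 20.9),
                                pct_obese = c(9.1, 9.6, 13.4, 15.0, 12.4, 11.7),
                                population_total = 260000) {
  w <- data.frame(wave = seq_along(age_lo), age_lo = as.integer(age_lo),
                  age_hi = as.integer(age_lo) + 1L, mean_bmi = mean_bmi,
                  pct_overweight = pct_overweight, pct_obese = pct_obese)
  if (nrow(w) > 1 && any(diff(w$age_lo) != 2L))
    stop("wave ages must increase by exactly 2 years")
  if (any(w$pct_overweight < 0 | w$pct_obese < 0 |
          w$pct_overweight + w$pct_obese > 100))
    stop("prevalences must be in [0, 100] and sum to at most 100")
  if (any(w$mean_bmi <= 10)) stop("mean_bmi must exceed 10 kg/m^2")
  structure(list(waves = w, population_total = population_total),
            class = "calibration_targets")
}

#' Generator configuration
#'
#' Settings of the synthetic-cohort generator. Defaults describe the cohort
#' the package emulates: 4,983 children first measured at ages 4/5,
#' followed biennially, with ~7% loss to follow-up per wave (about 30% by
#' the sixth wave) and survey weights with coefficient of variation 0.3
#' scaling to the target population. The stratum/PSU structure is synthetic
#' (8 strata of 4 primary sampling units) since real design identifiers are
#' unavailable.
#'
#' @param n_children Number of children in the baseline cross-section.
#' @param seed Integer seed; everything the generator draws is reproducible
#'   from it.
#' @param sex_ratio Proportion male.
#' @param attrition_per_wave Per-wave Bernoulli dropout probability (monotone:
#'   once absent, always absent).
#' @param contamination_rate Proportion of records replaced by implausible
#'   BMI values (|z-score| > 5), emulating data-entry errors.
#' @param sex_offset Baseline male-female difference in mean BMI, kg/m^2,
#'   applied symmetrically (+/- half) around the pooled target.
#' @param rho Latent tracking correlation between consecutive waves of the
#'   Gaussian copula that links a child's BMI ranks over time.
#' @param weight_cv Coefficient of variation of the gamma survey weights.
#' @param n_strata,psus_per_stratum Survey-design shape.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_children = 4983, seed = 1L, sex_ratio = 0.51,
                             attrition_per_wave = 0.07,
                             contamination_rate = 0,
                             sex_offset = 0.1, rho = 0.9, weight_cv = 0.3,
                             n_strata = 8L, psus_per_stratum = 4L) {
  stopifnot(attrition_per_wave >= 0, attrition_per_wave < 1,
            contamination_rate >= 0, contamination_rate < 1,
            sex_ratio > 0, sex_ratio < 1, rho > -1, rho < 1, weight_cv > 0)
  if (n_children < 2 * n_strata * psus_per_stratum)
    stop("n_children must be at least 2 x n_strata x psus_per_stratum ",
         "(variance estimation needs >= 2 records per PSU)")
  structure(list(n_children = as.integer(n_children), seed = as.integer(seed),
                 sex_ratio = sex_ratio, attrition_per_wave = attrition_per_wave,
                 contamination_rate = contamination_rate,
                 sex_offset = sex_offset, rho = rho, weight_cv = weight_cv,
                 n_strata = as.integer(n_strata),
                 psus_per_stratum = as.integer(psus_per_stratum)),
            class = "generator_config")
}

# marginal shifted-lognormal parameters for one wave, per (sex, single age)
.wave_marginals <- function(targets, wave, config, ref, cutoffs = status_cutoffs()) {
  tw <- targets$waves[wave, ]
  out <- list()
  for (sx in c("M", "F")) {
    off <- if (sx == "M") config$sex_offset / 2 else -config$sex_offset / 2
    for (a in c(tw$age_lo, tw$age_hi)) {
      par <- tryCatch(
        calibrate_bmi_distribution(tw$mean_bmi + off, tw$pct_overweight,
                                   tw$pct_obese, a, sx, ref, cutoffs),
        error = function(e) stop("calibration failed for wave ", wave,
                                 " (age ", a, ", sex ", sx, "): ",
                                 conditionMessage(e), call. = FALSE))
      out[[paste0(sx, a)]] <- par
    }
  }
  out
}

# Supremum of the representable z-score at each (age, sex): for L < 0 the
# LMS transform approaches -1/(L*S) from below as BMI grows, so very large
# positive z-scores may be unrepresentable at ages with strong skew.
.z_cap <- function(age, sex, ref) {
  p <- .lms_at(age_to_months(age), sex, ref)
  ifelse(p$L < 0, -1 / (p$L * p$S), Inf)
}

# Clamp clean draws strictly inside the plausible band |z| < z_limit, so
# that implausible records come only from explicit contamination.
.clamp_plausible <- function(bmi, age, sex, ref, z_limit = 4.9) {
  hi_z <- pmin(z_limit, .z_cap(age, sex, ref) - 0.2)
  hi <- zscore_to_bmi(hi_z, age, sex, ref)
  lo <- zscore_to_bmi(-z_limit, age, sex, ref)
  pmin(pmax(bmi, lo), hi)
}

# replace a fraction of present records with implausible BMIs (|z| > 5);
# where z > +5 is unrepresentable (strong reference skew), contamination
# goes to the low side instead. Returns list(bmi, hit).
.contaminate <- function(bmi, age, sex, rate, ref) {
  hit <- stats::runif(length(bmi)) < rate & !is.na(bmi)
  if (any(hit)) {
    i <- which(hit)
    z <- sample(c(-1, 1), length(i), TRUE) * stats::runif(length(i), 5.6, 7.5)
    cap <- .z_cap(age[i], sex[i], ref)
    z <- ifelse(z > 0 & z > cap - 0.3, -z, z)
    bmi[i] <- zscore_to_bmi(z, age[i], sex[i], ref)
  }
  list(bmi = bmi, hit = hit)
}

#' Generate a calibrated baseline (wave 1) cohort
#'
#' Draws a synthetic cross-section of children at the first wave's age pair.
#' Ages are sampled uniformly over the two integer ages; sex by
#' `sex_ratio`; BMI from a shifted log-normal calibrated per (sex, age) so
#' that mean and weight-status tail prevalences reproduce the wave-1
#' targets; gamma survey weights (CV `weight_cv`) rescaled to sum exactly
#' to `population_total`; strata and PSUs assigned round-robin. Deterministic
#' given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param targets A [calibration_targets()].
#' @param ref LMS reference, [lms_reference()].
#' @return A cohort data frame (one row per child) with columns `child_id`,
#'   `wave`, `age_years`, `sex`, `bmi`, `weight`, `stratum`, `psu`,
#'   `ses_quintile`, `present`, plus attributes `bmi_clean` (pre-
#'   contamination values) and `contaminated` (row flags).
#' @export
#' @examples
#' coh <- generate_baseline(generator_config(n_children = 500))
#' sum(coh$weight)
generate_baseline <- function(config = generator_config(),
                              targets = calibration_targets(),
                              ref = lms_reference()) {
  set.seed(config$seed)
  n <- config$n_children
  sex <- sample(c("M", "F"), n, TRUE, c(config$sex_ratio, 1 - config$sex_ratio))
  tw <- targets$waves[1, ]
  age <- sample(c(tw$age_lo, tw$age_hi), n, TRUE)
  mar <- .wave_marginals(targets, 1, config, ref)
  g <- stats::rnorm(n)
  bmi <- numeric(n)
  for (key in names(mar)) {
    idx <- which(paste0(sex, age) == key)
    p <- mar[[key]]
    bmi[idx] <- qshlnorm(stats::pnorm(g[idx]), p[1], p[2], p[3])
  }
  bmi <- .clamp_plausible(bmi, age, sex, ref)
  shape <- 1 / config$weight_cv^2
  wt <- stats::rgamma(n, shape = shape, rate = shape)
  wt <- wt / sum(wt) * targets$population_total
  stratum <- ((seq_len(n) - 1L) %% config$n_strata) + 1L
  psu <- (((seq_len(n) - 1L) %/% config$n_strata) %% config$psus_per_stratum) + 1L
  ses <- sample(1:5, n, TRUE)
  cont <- .contaminate(bmi, age, sex, config$contamination_rate, ref)
  out <- data.frame(child_id = seq_len(n), wave = 1L, age_years = age,
                    sex = sex, bmi = cont$bmi, weight = wt, stratum = stratum,
                    psu = psu, ses_quintile = ses, present = TRUE,
                    stringsAsFactors = FALSE)
  attr(out, "bmi_clean") <- bmi
  attr(out, "contaminated") <- cont$hit
  attr(out, "latent") <- g
  out
}

#' Extend a baseline cohort to all waves (longitudinal follow-up)
#'
#' Simulates the biennial follow-up of a generated baseline: each child's
#' BMI rank evolves as a stationary Gaussian copula (AR(1) latent with
#' per-wave correlation `rho`), and each wave's BMI values are the inverse
#' CDF of that wave's calibrated marginal at the child's (sex, age). Each
#' wave's cross-section therefore reproduces its target mean and tail
#' prevalences by construction, while children track over time; because the
#' marginals grow increasingly right-skewed, so does the cohort. Monotone
#' attrition is applied per wave (absent children keep `bmi = NA`), and
#' contamination is injected per record at `contamination_rate`.
#'
#' @param baseline Output of [generate_baseline()] (same config/targets).
#' @inheritParams generate_baseline
#' @return Long cohort data frame over all target waves, same columns as
#'   [generate_baseline()], with attribute `contaminated` flagging injected
#'   implausible records.
#' @export
generate_longitudinal <- function(baseline, targets = calibration_targets(),
                                  config = generator_config(),
                                  ref = lms_reference()) {
  n_waves <- nrow(targets$waves)
  if (n_waves < 2) stop("targets must include at least two waves")
  n <- nrow(baseline)
  set.seed(config$seed + 1L)
  sex <- baseline$sex
  age0 <- baseline$age_years
  g <- attr(baseline, "latent")
  bmi_clean <- attr(baseline, "bmi_clean")
  if (is.null(bmi_clean)) bmi_clean <- baseline$bmi
  if (is.null(g)) { # recover latent ranks from wave-1 marginals, capped
    mar1 <- .wave_marginals(targets, 1, config, ref)
    g <- numeric(n)
    for (key in names(mar1)) {
      idx <- which(paste0(sex, age0) == key)
      p <- mar1[[key]]
      g[idx] <- stats::qnorm(pshlnorm(bmi_clean[idx], p[1], p[2], p[3]))
    }
    g <- pmin(pmax(g, -4), 4)
  }
  waves <- vector("list", n_waves)
  base_out <- baseline
  attr(base_out, "latent") <- NULL
  waves[[1]] <- base_out
  cont_flags <- attr(baseline, "contaminated")
  if (is.null(cont_flags)) cont_flags <- rep(FALSE, n)
  present <- rep(TRUE, n)
  for (w in 2:n_waves) {
    g <- config$rho * g + sqrt(1 - config$rho^2) * stats::rnorm(n)
    age <- age0 + 2L * (w - 1L)
    mar <- .wave_marginals(targets, w, config, ref)
    bmi <- numeric(n)
    for (key in names(mar)) {
      idx <- which(paste0(sex, age) == key)
      p <- mar[[key]]
      bmi[idx] <- qshlnorm(stats::pnorm(g[idx]), p[1], p[2], p[3])
    }
    bmi <- .clamp_plausible(bmi, age, sex, ref)
    present <- present & stats::runif(n) >= config$attrition_per_wave
    cont <- .contaminate(bmi, age, sex, config$contamination_rate, ref)
    obs <- cont$bmi
    obs[!present] <- NA_real_
    row <- data.frame(child_id = baseline$child_id, wave = as.integer(w),
                      age_years = age, sex = sex, bmi = obs,
                      weight = baseline$weight, stratum = baseline$stratum,
                      psu = baseline$psu, ses_quintile = baseline$ses_quintile,
                      present = present, stringsAsFactors = FALSE)
    cont_flags <- c(cont_flags, cont$hit & present)
    waves[[w]] <- row
  }
  out <- do.call(rbind, waves)
  rownames(out) <- NULL
  attr(out, "contaminated") <- cont_flags
  out
}
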