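# Shared fixtures, all built in code.

# constant-coefficient LMS reference: L = -1.6, M = 16, S = 0.1 at every
# age, both sexes -- makes z-score arithmetic transparent in tests
flat_lms <- function(L = -1.6, M = 16, S = 0.1) {
  expand.grid(sex = c("M", "F"), age_months = c(48L, 191L),
              stringsAsFactors = FALSE)[, c("sex", "age_months")] |>
    transform(L = L, M = M, S = S)
}

# minimal valid cohort rows
make_cohort <- function(child_id, wave, age_years, sex, bmi,
                        weight = 1, stratum = 1L, psu = child_id) {
  data.frame(child_id = child_id, wave = as.integer(wave),
             age_years = age_years, sex = sex, bmi = bmi, weight = weight,
             stratum = stratum, psu = psu, ses_quintile = 3L,
             present = !is.na(bmi), stringsAsFactors = FALSE)
}

# a baseline cross-section of n children ready for run_simulation()
make_baseline <- function(n = 50, seed = 1, bmi_mean = 16.5, bmi_sd = 1) {
  set.seed(seed)
  data.frame(child_id = seq_len(n),
             sex = rep_len(c("M", "F"), n),
             age_years = rep_len(c(4L, 5L), n),
             bmi = pmax(stats::rnorm(n, bmi_mean, bmi_sd), 12),
             weight = stats::runif(n, 0.5, 1.5),
             stratum = rep_len(1:2, n),
             psu = rep_len(1:8, n), stringsAsFactors = FALSE)
}

# single-segment deterministic equation set covering both sexes
simple_equations <- function(beta0 = 0.6, beta_age = 0, beta_bmi = 0,
                             resid_sd = 0, resid_sd_slope = 0) {
  growth_equation_set(sex = c("M", "F"), age_lo = 4, age_hi = 16,
                      beta0 = beta0, beta_age = beta_age, beta_bmi = beta_bmi,
                      resid_sd = resid_sd, resid_sd_slope = resid_sd_slope,
                      delta_t = 1)
}

# small generator config for fast tests (keeps the design-minimum margin)
small_config <- function(n = 600, seed = 1, ...) {
  generator_config(n_children = n, seed = seed, attrition_per_wave = 0, ...)
}
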