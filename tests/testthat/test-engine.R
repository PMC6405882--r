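test_that("zero-residual engine matches the closed-form affine recursion", {
  # independent oracle: b_{t+1} = beta0 + beta_age * a_t + (1 + beta_bmi) * b_t
  set.seed(5)
  for (rep in 1:5) {
    beta <- c(runif(1, 0.5, 2.5), runif(1, -0.1, 0.1), runif(1, -0.08, 0.02))
    eqs <- simple_equations(beta[1], beta[2], beta[3])
    base <- make_baseline(n = 20, seed = rep)
    traj <- run_simulation(base, eqs, NULL, list(),
                           engine_config(n_cycles = 10,
                                         stochastic_residual = FALSE))
    for (i in c(1, 7, 20)) {
      b <- base$bmi[i]; a <- base$age_years[i]
      for (t in 1:10) {
        b <- max(beta[1] + beta[2] * a + (1 + beta[3]) * b, 10)
        a <- a + 1
      }
      got <- traj$panel$bmi[traj$panel$child_id == i & traj$panel$cycle == 10]
      expect_equal(got, b, tolerance = 1e-10)
    }
  }
})

test_that("zero hazard conserves the population; mortality calibrates binomially", {
  base <- make_baseline(n = 400)
  eqs <- simple_equations()
  traj <- run_simulation(base, eqs, zero_life_table(),
                         config = engine_config(n_cycles = 10,
                                                stochastic_residual = FALSE))
  alive <- tapply(traj$panel$alive, traj$panel$cycle, sum)
  expect_true(all(alive == 400))
  # q fixed at 1e-4: deaths over 10 cycles within 3 binomial SDs
  lt <- zero_life_table(); lt$q <- 1e-4
  set.seed(31)
  deaths <- sum(vapply(1:30, function(s) {
    tr <- run_simulation(base, eqs, lt,
                         config = engine_config(n_cycles = 10, seed = s,
                                                stochastic_residual = FALSE))
    400L - sum(tr$panel$alive[tr$panel$cycle == 10])
  }, 0L))
  expected <- 30 * 400 * (1 - (1 - 1e-4)^10)
  expect_lt(abs(deaths - expected), 3 * sqrt(expected))
  # alive count is non-increasing
  expect_error(run_simulation(base, eqs, zero_life_table(ages = 4:6)),
               "life table missing")
})

test_that("simulation is seed-deterministic and cycle 0 equals annotated input", {
  base <- make_baseline(n = 60)
  eqs <- simple_equations(0.6, 0, 0, resid_sd = 0.3)
  t1 <- run_simulation(base, eqs, config = engine_config(n_cycles = 5, seed = 4))
  t2 <- run_simulation(base, eqs, config = engine_config(n_cycles = 5, seed = 4))
  expect_identical(t1$panel, t2$panel)
  t3 <- run_simulation(base, eqs, config = engine_config(n_cycles = 5, seed = 9))
  expect_false(identical(t1$panel$bmi, t3$panel$bmi))
  t0 <- run_simulation(base, eqs, config = engine_config(n_cycles = 0))
  expect_equal(nrow(t0$panel), nrow(base))
  expect_equal(t0$panel$bmi, base$bmi)
  expect_equal(t0$panel$z, bmi_zscore(base$bmi, base$age_years, base$sex))
})

test_that("intervention overlay shifts the trajectory by the decayed effect", {
  base <- make_baseline(n = 30)
  eqs <- simple_equations(0.8, 0, 0)
  cfg <- engine_config(n_cycles = 8, stochastic_residual = FALSE)
  spec <- intervention_spec(effect = 0.3, duration = 3, start_cycle = 2,
                            eligible_age_lo = 4, eligible_age_hi = 15)
  ctrl <- run_simulation(base, eqs, config = cfg)
  arm <- run_simulation(base, eqs, interventions = list(spec), config = cfg)
  diff <- tapply(ctrl$panel$bmi - arm$panel$bmi, ctrl$panel$cycle, mean)
  # no effect before start, then exactly e per active year, then constant gap
  expect_equal(as.numeric(diff), c(0, 0, 0, 0.3, 0.6, 0.9, 0.9, 0.9, 0.9),
               tolerance = 1e-12)
  expect_equal(nrow(arm$enrollments), 30)
})

test_that("decay kinds follow their closed forms", {
  sp <- intervention_spec(effect = 0.4, duration = 5, decay = "none")
  expect_equal(apply_intervention_effect(sp, c(0, 4.99, 5, 7)),
               c(0.4, 0.4, 0, 0))
  lin <- intervention_spec(effect = 0.4, duration = 4, decay = "linear")
  expect_equal(apply_intervention_effect(lin, c(0, 1, 3)),
               0.4 * (1 - c(0, 1, 3) / 4))
  ex <- intervention_spec(effect = 0.4, duration = 10, decay = "exponential",
                          half_life = 2)
  expect_equal(apply_intervention_effect(ex, 2), 0.2) # one half-life
  expect_equal(apply_intervention_effect(ex, 4), 0.1)
})

test_that("status-restricted eligibility enrolls only matching children", {
  base <- make_baseline(n = 40, bmi_mean = 17, bmi_sd = 3)
  z <- bmi_zscore(base$bmi, base$age_years, base$sex)
  n_obese <- sum(classify_status(z) == "obese")
  spec <- intervention_spec(effect = 0.2, duration = 2,
                            eligible_statuses = "obese", start_cycle = 0)
  traj <- run_simulation(base, simple_equations(), interventions = list(spec),
                         config = engine_config(n_cycles = 2,
                                                stochastic_residual = FALSE))
  expect_equal(nrow(traj$enrollments), n_obese)
  expect_gt(n_obese, 0)
})

test_that("stronger never-decaying effects never increase BMI (monotone dose)", {
  base <- make_baseline(n = 25)
  eqs <- simple_equations(0.7, 0.02, -0.01)
  cfg <- engine_config(n_cycles = 6, stochastic_residual = FALSE)
  get_bmi <- function(e) {
    sp <- intervention_spec(effect = e, duration = 6, start_cycle = 0)
    run_simulation(base, eqs, interventions = list(sp), config = cfg)$panel$bmi
  }
  b_lo <- get_bmi(0.1); b_hi <- get_bmi(0.3)
  expect_true(all(b_hi <= b_lo + 1e-12))
})

test_that("biennial fits are annualized consistently (two cycles = one wave step)", {
  # for delta_t = 2 equations the two-cycle deterministic update must equal
  # the fitted biennial map b + 2 * (beta0 + beta_age * a + beta_bmi * b)
  eqs <- growth_equation_set("M", 4, 16, beta0 = 1.2, beta_age = -0.02,
                             beta_bmi = -0.03, delta_t = 2)
  base <- data.frame(child_id = 1:3, sex = "M", age_years = c(4, 6, 8),
                     bmi = c(14, 17, 22), weight = 1, stratum = 1, psu = 1:3)
  traj <- run_simulation(base, eqs,
                         config = engine_config(n_cycles = 2,
                                                stochastic_residual = FALSE))
  b2 <- traj$panel$bmi[traj$panel$cycle == 2]
  expected <- base$bmi + 2 * (1.2 - 0.02 * base$age_years - 0.03 * base$bmi)
  expect_equal(b2, expected, tolerance = 1e-10)
  # with annualize = FALSE the literal recursion applies instead
  tr2 <- run_simulation(base, eqs,
                        config = engine_config(n_cycles = 2,
                                               stochastic_residual = FALSE,
                                               annualize = FALSE))
  lit <- base$bmi
  a <- base$age_years
  for (t in 1:2) {
    lit <- lit + 1.2 - 0.02 * a - 0.03 * lit
    a <- a + 1
  }
  expect_equal(tr2$panel$bmi[tr2$panel$cycle == 2], lit, tolerance = 1e-10)
})

test_that("endpoint skewness exceeds baseline skewness with BMI-dependent residuals", {
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  eqs <- growth_equation_set("M", 4, 16, beta0 = 0.6, beta_age = 0,
                             beta_bmi = 0, resid_sd = 0.2,
                             resid_sd_slope = 0.025, delta_t = 1)
  eqs <- rbind(eqs, transform(eqs, sex = "F"))
  class(eqs) <- c("growth_equation_set", "data.frame")
  hits <- vapply(1:20, function(s) {
    base <- make_baseline(n = 500, seed = 1) # same cohort, engine seed varies
    traj <- run_simulation(base, eqs,
                           config = engine_config(n_cycles = 10, seed = s))
    p <- traj$panel
    skew(p$bmi[p$cycle == 10]) > skew(p$bmi[p$cycle == 0])
  }, NA)
  expect_gte(mean(hits), 0.95)
})
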