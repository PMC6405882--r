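test_that("discount factors follow the beyond-one-year convention", {
  expect_equal(discount_factor(c(0, 0.5, 3, 10), 0), rep(1, 4))
  expect_equal(discount_factor(2, 0.05), 1.05^-2)
  expect_equal(discount_factor(0.99, 0.05), 1)
  t <- seq(0, 12, by = 0.25)
  expect_true(all(diff(discount_factor(t, 0.07)) <= 0))
  expect_error(discount_factor(1, -0.01), "non-negative")
})

test_that("full-health undiscounted QALYs equal cycles survived", {
  base <- make_baseline(n = 30)
  traj <- run_simulation(base, simple_equations(),
                         config = engine_config(n_cycles = 10,
                                                stochastic_residual = FALSE))
  ut <- utility_table(utility = rep(1, 4))
  q <- accumulate_qalys(traj, ut, econ_config(discount_rate = 0))
  expect_equal(q$per_individual$qalys, rep(10, 30))
  expect_equal(q$estimate$point, 10)
})

test_that("discounted QALY and cost streams match geometric closed forms", {
  base <- make_baseline(n = 12)
  traj <- run_simulation(base, simple_equations(),
                         config = engine_config(n_cycles = 10,
                                                stochastic_residual = FALSE))
  r <- 0.05
  q <- accumulate_qalys(traj, utility_table(utility = rep(1, 4)),
                        econ_config(discount_rate = r))
  closed <- 1 + sum(1.05^-(1:9))
  expect_equal(q$per_individual$qalys, rep(closed, 12), tolerance = 1e-10)
  ct <- cost_table(annual_cost = rep(100, 4))
  cc <- accumulate_costs(traj, ct, econ_config(discount_rate = r))
  expect_equal(cc$per_individual$cost, rep(100 * closed, 12), tolerance = 1e-10)
  # discounted <= undiscounted, equality only at rate 0
  c0 <- accumulate_costs(traj, ct, econ_config(discount_rate = 0))
  expect_true(all(cc$per_individual$cost < c0$per_individual$cost))
  expect_equal(c0$per_individual$cost, rep(1000, 12))
})

test_that("death gates all later contributions to exactly zero", {
  base <- make_baseline(n = 50)
  lt <- zero_life_table(); lt$q <- 0.15 # high hazard to force deaths
  traj <- run_simulation(base, simple_equations(), lt,
                         config = engine_config(n_cycles = 10, seed = 2,
                                                stochastic_residual = FALSE))
  p <- traj$panel
  died <- vapply(split(p, p$child_id), function(d) any(!d$alive), NA)
  expect_gt(sum(died), 0)
  q <- accumulate_qalys(traj, utility_table(utility = rep(1, 4)),
                        econ_config(discount_rate = 0))
  # per-child QALYs equal the number of cycles 0..9 spent alive
  lived <- vapply(split(p, p$child_id),
                  function(d) sum(d$alive[d$cycle < 10]), 0L)
  expect_equal(q$per_individual$qalys,
               unname(lived[as.character(q$per_individual$child_id)]))
})

test_that("intervention delivery costs land on enrollees, discounted", {
  base <- make_baseline(n = 20)
  sp <- intervention_spec(effect = 0.1, duration = 2, start_cycle = 0,
                          cost_per_participant = 500)
  traj <- run_simulation(base, simple_equations(), interventions = list(sp),
                         config = engine_config(n_cycles = 5,
                                                stochastic_residual = FALSE))
  cc <- accumulate_costs(traj, cost_table(), econ_config(discount_rate = 0.05))
  expect_equal(cc$per_individual$cost, rep(500, 20)) # cycle 0 undiscounted
  sp1 <- intervention_spec(effect = 0.1, duration = 2, start_cycle = 3,
                           cost_per_participant = 500)
  traj1 <- run_simulation(base, simple_equations(), interventions = list(sp1),
                          config = engine_config(n_cycles = 5,
                                                 stochastic_residual = FALSE))
  cc1 <- accumulate_costs(traj1, cost_table(), econ_config(discount_rate = 0.05))
  expect_equal(cc1$per_individual$cost, rep(500 * 1.05^-3, 20),
               tolerance = 1e-12)
})

test_that("societal perspective adds indirect costs for every individual", {
  base <- make_baseline(n = 15)
  traj <- run_simulation(base, simple_equations(),
                         config = engine_config(n_cycles = 6,
                                                stochastic_residual = FALSE))
  ct <- cost_table(annual_cost = rep(50, 4), indirect_cost = rep(20, 4))
  payer <- accumulate_costs(traj, ct, econ_config(perspective = "payer"))
  soc <- accumulate_costs(traj, ct, econ_config(perspective = "societal"))
  expect_true(all(soc$per_individual$cost >= payer$per_individual$cost))
})

test_that("ICER arithmetic, dominance labels and scale equivariance", {
  arm <- function(cost, q) structure(list(mean_cost = cost, mean_qalys = q,
                                          endpoint_mean_bmi = 22,
                                          endpoint_mean_z = 1),
                                     class = "arm_result")
  ic <- compute_icer(arm(2000, 11), arm(1000, 10))
  expect_equal(ic$ratio, 1000)
  expect_equal(ic$dominance, "none")
  same <- compute_icer(arm(1000, 10), arm(1000, 10))
  expect_equal(same$dominance, "indeterminate")
  expect_true(is.na(same$ratio))
  dom <- compute_icer(arm(500, 11), arm(1000, 10))
  expect_equal(dom$dominance, "dominant")
  expect_true(is.na(dom$ratio))
  domd <- compute_icer(arm(1500, 9), arm(1000, 10))
  expect_equal(domd$dominance, "dominated")
  # multiplying all costs by k multiplies the ratio by k
  ic10 <- compute_icer(arm(20000, 11), arm(10000, 10))
  expect_equal(ic10$ratio, 10 * ic$ratio)
})

test_that("common random numbers: zero-effect arms are exactly equal", {
  base <- make_baseline(n = 40)
  eqs <- simple_equations(0.6, 0, 0, resid_sd = 0.3)
  sp <- intervention_spec(effect = 0, duration = 2, cost_per_participant = 0)
  res <- run_paired_arms(base, eqs, sp,
                         engine = engine_config(n_cycles = 8, seed = 6))
  expect_equal(res$icer$delta_cost, 0)
  expect_equal(res$icer$delta_effect, 0)
  expect_equal(res$icer$dominance, "indeterminate")
})

test_that("sensitivity scan brackets the base case and collapses exactly", {
  base <- make_baseline(n = 40)
  eqs <- simple_equations(0.7, 0, -0.01)
  sp <- intervention_spec(effect = 0.2, duration = 3,
                          cost_per_participant = 100)
  tab <- sensitivity_scan(base, eqs, sp,
                          engine = engine_config(n_cycles = 8,
                                                 stochastic_residual = FALSE),
                          metric = "bmi",
                          effect_range = c(0.1, 0.2, 0.3),
                          discount_range = c(0.03))
  expect_equal(nrow(tab), 5)
  # a range collapsed to the base value reproduces the base ICER exactly
  expect_equal(tab$delta_effect[tab$scenario == "effect=0.2"],
               tab$delta_effect[tab$scenario == "base"])
  # effect bounds bracket the base-case effect delta (deterministic mode)
  de <- tab$delta_effect
  expect_lt(de[tab$scenario == "effect=0.1"], de[tab$scenario == "base"])
  expect_gt(de[tab$scenario == "effect=0.3"], de[tab$scenario == "base"])
})

test_that("missing utility coverage raises a named error", {
  base <- make_baseline(n = 10, bmi_mean = 25, bmi_sd = 4) # some obese
  traj <- run_simulation(base, simple_equations(),
                         config = engine_config(n_cycles = 3,
                                                stochastic_residual = FALSE))
  ut <- utility_table()[1:2, ] # drop overweight/obese rows
  expect_error(accumulate_qalys(traj, ut), "no row covering")
})
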