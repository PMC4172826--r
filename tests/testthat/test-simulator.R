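test_that("the nutrient-response multiplier reproduces the fitted
           coupling arithmetic", {
  expect_equal(nutrient_modifier(0, 0.5, 2), 1)
  expect_equal(nutrient_modifier(0, 0.0069, 3.14), 1)
  expect_equal(nutrient_modifier(2, 1, 1), 3)
  # direct evaluation at the starvation + BAF operating point
  expect_equal(nutrient_modifier(17.1, 0.0069, 3.14), 52.34,
               tolerance = 0.005)
  expect_error(nutrient_modifier(-1, 1, 1), "delta")
})

test_that("effective rates apply nutrient modifiers, BAF attenuation and
           the lysosomal positioning slope", {
  p <- integrative_params()
  # zero deficit, no BAF: everything at base values
  r0 <- effective_rates(p, 0, condition("FM"))
  expect_equal(r0$pp_creation, 0.44)
  expect_equal(r0$ly_creation, 1.23)
  expect_equal(r0$al_degradation, 0.15)
  expect_equal(r0$ly_toward_nucleus, 0.55)
  expect_equal(r0$ap_toward_nucleus, 0.85)

  # starvation + BAF: relative AL degradation 0.05*(0.0069*17.1^3.14 + 1)
  rb <- effective_rates(p, 17.1, condition("ND", baf = TRUE))
  expect_equal(rb$al_degradation / p$al_degradation_rate, 2.61,
               tolerance = 0.01)

  # +0.5 percentage points of inward lysosome bias per deficit unit
  r44 <- effective_rates(p, 4.4, condition("FM", baf = TRUE))
  expect_equal(r44$ly_toward_nucleus, 0.572, tolerance = 1e-12)

  # transport override flows through the condition
  ro <- effective_rates(p, 0, condition("FM",
                                        ap_toward_nucleus_override = 0.79))
  expect_equal(ro$ap_toward_nucleus, 0.79)

  # core variant under BAF: the sampled AL lifetime mean is scaled x20
  pc <- core_params()
  rc <- effective_rates(pc, 0, condition("FM", baf = TRUE))
  expect_equal(rc$al_lifetime_mean, 95 / 0.05)
})

test_that("initialisation places the published census deterministically", {
  p <- integrative_params()
  st <- initialize_state(p, condition("FM"), default_grid, seed = 5)
  expect_identical(unname(tabulate(st$pool$kind, 4)), c(3L, 31L, 19L, 28L))
  st2 <- initialize_state(p, condition("FM"), default_grid, seed = 5)
  expect_pool_equal(st$pool, st2$pool, tol = 0)
  expect_error(initialize_state(integrative_params(agent_cap = 50),
                                condition("FM"), default_grid, seed = 1),
               "agent_cap")
})

test_that("a tick with all rates and probabilities zeroed changes nothing
           but the clock", {
  p <- integrative_params(
    pp_creation_rate = 0, ly_creation_rate = 0, al_degradation_rate = 0,
    pp_growth = 0, ap_growth = 0, ly_growth = 0, al_growth = 0,
    movement_speed = 0, ap_ly_fusion = 0, fusion_non_al_al = 0,
    fusion_al_al = 0, border_influx = 0, free_decay = 0,
    conversion_rate = 0, ly_recycling = 0, ap_uptake = 0, al_release = 0,
    free_diffusion = 0, bound_diffusion = 0,
    pp_maturation_mean = 1e9, ly_lifetime_mean = 1e9)
  cond <- condition("FM")
  st <- initialize_state(p, cond, default_grid, seed = 2)
  for (engine in c("cpp", "r")) {
    st1 <- tick(st, p, cond, default_grid, engine = engine)
    expect_equal(st1$tick, 1)
    expect_pool_equal(st1$pool, st$pool, tol = 0)
    expect_equal(st1$field$free, st$field$free)
  }
})

test_that("creation events are Poisson with the stated rate", {
  # everything frozen except phagophore creation at 0.42 per minute
  p <- core_params(
    initial_pp = 0, initial_ap = 0, initial_ly = 0, initial_al = 0,
    ly_creation_rate = 0, pp_growth = 0, movement_speed = 0,
    pp_maturation_mean = 1e9, agent_cap = 5000)
  cond <- condition("FM")
  st <- initialize_state(p, cond, default_grid, seed = 17)
  for (t in 1:1000) st <- tick(st, p, cond, default_grid)
  expect_equal(pool_size(st$pool) / 1000, 0.42, tolerance = 0.15)
})

test_that("run bookkeeping: one record per tick, bit-identical reruns,
           and the abort rule trips past the agent cap", {
  p <- integrative_params()
  tc <- run_simulation(p, condition("FM"), duration = 60, seed = 9)
  expect_equal(nrow(tc), 61)
  expect_equal(tc$tick, 0:60)
  tc2 <- run_simulation(p, condition("FM"), duration = 60, seed = 9)
  expect_identical(as.data.frame(tc)[], as.data.frame(tc2)[])
  fs <- attr(tc, "final_state")
  expect_pool_equal(fs$pool, attr(tc2, "final_state")$pool, tol = 0)

  # census blows past 500 -> aborted with reason
  pb <- integrative_params(pp_creation_rate = 60)
  tb <- run_simulation(pb, condition("FM"), duration = 60, seed = 1)
  expect_true(attr(tb, "aborted"))
  expect_identical(attr(tb, "abort_reason"), "agent cap exceeded")
  expect_lt(nrow(tb), 61)
  expect_error(tick(attr(tb, "final_state"), pb, condition("FM"),
                    default_grid), "aborted")
})

test_that("the compiled and R engines produce identical trajectories", {
  p <- integrative_params()
  cond <- condition("ND")
  t1 <- run_simulation(p, cond, 80, seed = 14, engine = "cpp")
  t2 <- run_simulation(p, cond, 80, seed = 14, engine = "r")
  expect_equal(as.matrix(as.data.frame(t1)), as.matrix(as.data.frame(t2)),
               tolerance = 1e-10)
})

test_that("ensembles aggregate completed runs and are self-consistent
           across disjoint seed sets", {
  pc <- core_params()
  e1 <- run_ensemble(pc, condition("FM"), n_runs = 1, duration = 60,
                     seed = 3)
  tc <- run_simulation(pc, condition("FM"), 60, seed = 3)
  expect_equal(e1$mean, summary_stats(tc, 60))

  e60a <- run_ensemble(pc, condition("FM"), n_runs = 60, duration = 180,
                       seed = 1000)
  e60b <- run_ensemble(pc, condition("FM"), n_runs = 60, duration = 180,
                       seed = 9000)
  sem <- sqrt(e60a$sd^2 / 60 + e60b$sd^2 / 60)
  expect_true(all(abs(e60a$mean - e60b$mean) < 3.5 * sem + 1e-9))
  # quantile bands are available for every component
  expect_true(all(e60a$q25 <= e60a$q75))
  expect_equal(nrow(e60a$per_run), 60)
})

test_that("the long-term experiment sweeps a perturbation grid and
           reports one endpoint summary per level", {
  p <- integrative_params()
  res <- longterm_experiment(p, condition("FM"), "ap_toward_nucleus",
                             levels = c(0.79, 0.85, 0.91), duration = 60,
                             n_runs = 3, seed = 4)
  expect_equal(nrow(res), 3)
  expect_equal(res$level, c(0.79, 0.85, 0.91))
  expect_true(all(c("count_ap", "size_al", "count_pp") %in% names(res)))
})
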