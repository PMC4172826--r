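test_that("spawned agents take the kind's initial size and sampled
           durations with the stated means", {
  pi_ <- integrative_params()
  pc <- core_params()
  g <- default_grid

  set.seed(1)
  expect_equal(spawn_agent("PP", pi_, g, 0)$size, 0.07)
  expect_equal(spawn_agent("LY", pi_, g, 0)$size, 0.1)
  expect_equal(spawn_agent("AL", pi_, g, 0)$size, 0.225)
  expect_equal(spawn_agent("PP", pc, g, 0)$size, 0.06)
  expect_equal(spawn_agent("LY", pc, g, 0)$size, 0.095)
  expect_error(spawn_agent("XX", pc, g, 0))

  # exponential-mean oracle for maturation times and lysosome lifetimes
  set.seed(7)
  pp <- spawn_agent("PP", pc, g, 0, n = 1e4)
  expect_equal(mean(pp$mat_time), 7.5, tolerance = 0.05)
  ly <- spawn_agent("LY", pc, g, 0, n = 1e4)
  expect_equal(mean(ly$lifetime), 18, tolerance = 0.05)

  # fixed-duration mode uses the mean itself
  pf <- core_params(lifetime_distribution = "fixed")
  set.seed(1)
  expect_equal(spawn_agent("PP", pf, g, 0, n = 3)$mat_time, rep(7.5, 3))
})

test_that("movement is 2 um per tick: radial with the stated inward bias
           for AP/LY, random direction for PP/AL, clamped at boundaries", {
  p <- core_params()
  g <- default_grid
  cond <- condition("FM")

  # colinear geometry: inward AP step from (10, 0) lands at (8, 0)
  r1 <- effective_rates(core_params(ap_toward_nucleus = 1,
                                    ly_toward_nucleus = 1), 0, cond)
  ap <- make_pool("AP", 10, 0)
  expect_equal(unlist(step_movement(ap, r1, p, g)[c("x", "y")]),
               c(x = 8, y = 0), tolerance = 1e-12)
  # boundary clamp: inward LY step from (6, 0) stops at (5, 0)
  lyp <- make_pool("LY", 6, 0)
  expect_equal(unlist(step_movement(lyp, r1, p, g)[c("x", "y")]),
               c(x = 5, y = 0), tolerance = 1e-12)

  # inward fraction matches the 85% transport probability
  rates <- effective_rates(p, 0, cond)
  set.seed(3)
  th <- stats::runif(1e4, 0, 2 * pi)
  pool <- make_pool(rep("AP", 1e4), 10 * cos(th), 10 * sin(th))
  moved <- step_movement(pool, rates, p, g)
  frac_in <- mean(sqrt(moved$x^2 + moved$y^2) < 10)
  expect_equal(frac_in, 0.85, tolerance = 0.02)

  # random walkers take steps of length 2 and stay in the annulus
  set.seed(4)
  rw <- make_pool(rep(c("PP", "AL"), 500), 10 * cos(th[1:1000]),
                  10 * sin(th[1:1000]))
  moved <- step_movement(rw, rates, p, g)
  d <- sqrt((moved$x - rw$x)^2 + (moved$y - rw$y)^2)
  r <- sqrt(moved$x^2 + moved$y^2)
  expect_true(all(d <= 2 + 1e-9))
  expect_true(all(r >= 5 - 1e-9 & r <= 15 + 1e-9))
})

test_that("growth adds the kind's rate per minute", {
  pc <- core_params()
  pp <- make_pool("PP", 8, 0, size = 0.06)
  expect_equal(step_growth(pp, pc)$size, 0.0606)
  ap <- make_pool("AP", 8, 0, size = 0.1)
  expect_equal(step_growth(ap, pc)$size, 0.10008)
  p0 <- core_params(pp_growth = 0)
  expect_equal(step_growth(pp, p0)$size, 0.06)
})

test_that("phagophores mature into autophagosomes when their sampled
           maturation time elapses", {
  pp <- make_pool("PP", 8, 0, size = 0.09, birth = 0, mat_time = 7.5)
  aged <- maturation_check(pp, 8)
  expect_identical(aged$kind, agent_kinds[["AP"]])
  expect_equal(aged$size, 0.09)   # size preserved
  expect_equal(aged$cargo, 0)
  young <- maturation_check(pp, 3)
  expect_identical(young$kind, agent_kinds[["PP"]])
})

test_that("fusion combines co-located partners additively with the stated
           probabilities", {
  pc <- core_params()
  rates <- effective_rates(pc, 0, condition("FM"))
  g <- default_grid

  # AP + LY forms a new AL: sizes add, the AP's cargo carries over
  pool <- make_pool(c("AP", "LY"), x = c(10, 10.2), y = 0,
                    size = c(0.10, 0.095), cargo = c(4, 0))
  set.seed(1)
  fused <- resolve_fusions(pool, rates, pc, tick = 5, grid = g)
  expect_equal(pool_size(fused), 1L)
  expect_identical(fused$kind, agent_kinds[["AL"]])
  expect_equal(fused$size, 0.195)
  expect_equal(fused$cargo, 4)
  expect_equal(fused$formed, 5)

  # agents 3 um apart cannot fuse
  apart <- make_pool(c("AP", "LY"), x = c(8, 11), y = 0)
  set.seed(1)
  expect_equal(pool_size(resolve_fusions(apart, rates, pc, 1, g)), 2L)

  # LY + AL fusion frequency matches the 45% chance: 3000 isolated pairs
  big <- build_grid(200, 0, 0.5)
  k <- 2000   # isolated pairs on a 4-um grid, partners 0.3 um apart
  gx <- rep(seq(-90, 90, by = 4), length.out = k)
  gy <- rep(seq(-90, 90, by = 4), each = 46)[seq_len(k)]
  pool <- make_pool(rep(c("LY", "AL"), k),
                    x = as.vector(rbind(gx, gx + 0.3)),
                    y = as.vector(rbind(gy, gy)),
                    formed = as.vector(rbind(NA_real_, 0)),
                    lifetime = 1e6)
  set.seed(9)
  fused <- resolve_fusions(pool, rates, pc, 1, big)
  frac <- (2 * k - pool_size(fused)) / k
  expect_equal(frac, 0.45, tolerance = 0.04)

  # AL + AL: the earlier-formed vesicle survives, no rejuvenation
  r1 <- effective_rates(core_params(fusion_al_al = 1), 0, condition("FM"))
  two <- make_pool(c("AL", "AL"), x = c(10, 10.1), y = 0,
                   size = c(0.3, 0.2), formed = c(4, 2), lifetime = 50)
  set.seed(2)
  one <- resolve_fusions(two, r1, pc, 10, g)
  expect_equal(pool_size(one), 1L)
  expect_equal(one$formed, 2)
  expect_equal(one$size, 0.5)
})

test_that("fusion conserves total vesicle area and fuses each agent at
           most once per tick", {
  pc <- core_params()
  rates <- effective_rates(pc, 0, condition("FM"))
  g <- default_grid
  set.seed(11)
  for (k in 1:30) {
    n <- sample(5:25, 1)
    th <- stats::runif(n, 0, 2 * pi)
    r <- stats::runif(n, 5, 7)   # crowded ring: many candidate pairs
    pool <- make_pool(sample(c("AP", "LY", "AL"), n, replace = TRUE),
                      x = r * cos(th), y = r * sin(th),
                      size = stats::runif(n, 0.05, 0.3),
                      formed = 0, lifetime = 1e6)
    fused <- resolve_fusions(pool, rates, pc, 1, g)
    expect_equal(sum(fused$size), sum(pool$size), tolerance = 1e-12)
    # one fusion per agent per tick: the census can at most halve
    expect_gte(pool_size(fused), ceiling(n / 2))
  }
})

test_that("degradation releases remaining cargo on the patch and reforms
           a lysosome about half the time", {
  pc <- core_params()
  g <- default_grid

  # a dying AL credits its cargo to its patch
  r1 <- effective_rates(core_params(reformation_chance = 0), 0,
                        condition("FM"))
  al <- make_pool("AL", 10, 0, cargo = 7, formed = 0, lifetime = 3)
  set.seed(1)
  out <- degradation_step(al, r1, pc, g, tick = 10, next_id = 2L)
  expect_equal(pool_size(out$pool), 0L)
  expect_equal(out$released_amt, 7)
  expect_equal(out$released_idx,
               autophagosim:::.flux_patch_linear(g, 10, 0))

  # reformation chance 1: a fresh lysosome appears at the AL's position
  r2 <- effective_rates(core_params(reformation_chance = 1), 0,
                        condition("FM"))
  set.seed(1)
  out <- degradation_step(al, r2, pc, g, 10, 2L)
  expect_identical(out$pool$kind, agent_kinds[["LY"]])
  expect_equal(out$pool$size, pc$ly_initial_size)
  expect_equal(out$pool$x, 10)

  # ~50% of dying ALs reform (default chance)
  rates <- effective_rates(pc, 0, condition("FM"))
  many <- make_pool(rep("AL", 4000), x = 10, y = 0, formed = 0,
                    lifetime = 1)
  set.seed(5)
  out <- degradation_step(many, rates, pc, g, 10, 1L)
  expect_equal(pool_size(out$pool) / 4000, 0.5, tolerance = 0.03)

  # integrative mode with zero degradation probability: no AL deaths
  pi_ <- integrative_params(al_degradation_rate = 0)
  ri <- effective_rates(pi_, 0, condition("FM"))
  many$lifetime <- rep(NA_real_, 4000)
  set.seed(5)
  out <- degradation_step(many, ri, pi_, g, 10, 1L)
  expect_equal(pool_size(out$pool), 4000L)
})

test_that("only the allowed kind transitions occur in a simulation trace", {
  p <- integrative_params()
  cond <- condition("ND")
  g <- default_grid
  state <- initialize_state(p, cond, g, seed = 21)
  allowed <- list(PP = c("PP", "AP"), AP = c("AP", "AL"),
                  LY = c("LY", "AL"), AL = "AL")
  prev <- stats::setNames(names(agent_kinds)[state$pool$kind],
                          state$pool$id)
  violations <- character()
  for (t in 1:80) {
    state <- tick(state, p, cond, g)
    now <- stats::setNames(names(agent_kinds)[state$pool$kind],
                           state$pool$id)
    shared <- intersect(names(now), names(prev))
    bad <- shared[!mapply(function(id) now[[id]] %in% allowed[[prev[[id]]]],
                          shared)]
    violations <- c(violations,
                    sprintf("t=%d %s->%s", t, prev[bad], now[bad]))
    prev <- now
  }
  expect_length(violations, 0)
  # every agent stays inside the cytosolic annulus
  r <- sqrt(state$pool$x^2 + state$pool$y^2)
  expect_true(all(r >= 5 - 1e-9 & r <= 15 + 1e-9))
})
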