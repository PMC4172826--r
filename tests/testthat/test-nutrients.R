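test_that("field initialisation puts the stated means on every cytosol
           patch and nothing elsewhere", {
  p <- integrative_params()
  f <- init_field(default_grid, p)
  expect_equal(mean(f$free[default_grid$cytosol]), 20)
  expect_equal(mean(f$bound[default_grid$cytosol]), 20)
  expect_true(all(f$free[!default_grid$cytosol] == 0))
  f0 <- init_field(default_grid, integrative_params(free_init = 0,
                                                    bound_init = 0))
  expect_true(all(f0$free == 0) && all(f0$bound == 0))
})

test_that("one tick of fluxes follows the stated per-patch ledger", {
  p <- integrative_params()
  g <- default_grid
  f <- init_field(g, p)

  # border patch under full medium: 20 + 1.1 - 0.05 - 0.045 = 21.005
  out <- apply_fluxes(f, empty_pool(), p, condition("FM"), g)
  b <- which(g$border)[1]
  expect_equal(out$field$free[b], 21.005, tolerance = 1e-12)
  # bound gains the converted 0.045 everywhere
  expect_equal(out$field$bound[b], 20.045, tolerance = 1e-12)
  # interior patch: no influx
  interior <- setdiff(which(g$cytosol), which(g$border))[1]
  expect_equal(out$field$free[interior], 20 - 0.05 - 0.045,
               tolerance = 1e-12)

  # nutrient deprivation switches the influx off
  outnd <- apply_fluxes(f, empty_pool(), p, condition("ND"), g)
  expect_equal(outnd$field$free[b], 20 - 0.095, tolerance = 1e-12)

  # autophagosomal uptake is capped by availability (conversion and decay
  # disabled so the patch holds exactly 1.0 bound unit at the uptake step)
  p0 <- integrative_params(conversion_rate = 0, free_decay = 0)
  ap <- make_pool("AP", 10, 0)
  fl <- init_field(g, p0)
  idx <- autophagosim:::.flux_patch_linear(g, 10, 0)
  fl$bound[idx] <- 1.0
  got <- apply_fluxes(fl, ap, p0, condition("ND"), g)
  expect_equal(got$pool$cargo, 1.0)
  expect_equal(got$field$bound[idx], 0)

  # lysosomal recycling moves bound to free on the lysosome's patch
  ly <- make_pool("LY", -8, 3, lifetime = 100)
  idx2 <- autophagosim:::.flux_patch_linear(g, -8, 3)
  got <- apply_fluxes(f, ly, p, condition("ND"), g)
  expect_equal(got$field$bound[idx2], 20 + 0.045 - 1.5, tolerance = 1e-12)
})

test_that("diffusion spreads eight equal shares, retains off-cytosol
           shares, and conserves mass exactly", {
  p <- integrative_params()
  g <- default_grid
  f <- init_field(g, p)

  # a uniform field is a fixed point
  d <- diffuse(f, p, g)
  expect_equal(d$free, f$free, tolerance = 1e-12)

  # single interior patch with free 8: keeps 2.4, each neighbour gets 0.7
  f1 <- init_field(g, integrative_params(free_init = 0, bound_init = 0))
  ij <- autophagosim:::.patch_index(g, 10, 0)  # interior, 8 cyto neighbours
  i <- ij[1, 1] + 1; j <- ij[1, 2] + 1
  f1$free[i, j] <- 8
  d1 <- diffuse(f1, p, g)
  expect_equal(d1$free[i, j], 8 * 0.3, tolerance = 1e-12)
  expect_equal(d1$free[i + 1, j], 0.7, tolerance = 1e-12)
  expect_equal(d1$free[i - 1, j - 1], 0.7, tolerance = 1e-12)

  # mass conservation to 1e-9 on a rough random field
  set.seed(8)
  f2 <- f
  f2$free[g$cytosol] <- stats::runif(sum(g$cytosol), 0, 40)
  f2$bound[g$cytosol] <- stats::runif(sum(g$cytosol), 0, 40)
  d2 <- diffuse(f2, p, g)
  expect_equal(sum(d2$free), sum(f2$free), tolerance = 1e-9)
  expect_equal(sum(d2$bound), sum(f2$bound), tolerance = 1e-9)
  expect_true(all(d2$free >= 0) && all(d2$bound >= 0))
})

test_that("delta_nutrition is the floored shortfall of mean free
           nutrients below the baseline", {
  p <- integrative_params()
  f <- init_field(default_grid, p)
  expect_equal(delta_nutrition(f), 0)
  f$free[f$cytosol] <- 15.6
  expect_equal(delta_nutrition(f), 4.4, tolerance = 1e-12)
  f$free[f$cytosol] <- 25
  expect_equal(delta_nutrition(f), 0)
})

test_that("with influx, decay and conversion disabled the system is
           closed: free + bound + cargo is conserved and pools stay
           non-negative", {
  p <- integrative_params(border_influx = 0, free_decay = 0,
                          conversion_rate = 0)
  cond <- condition("FM")
  g <- default_grid
  state <- initialize_state(p, cond, g, seed = 31)
  total0 <- sum(state$field$free) + sum(state$field$bound) +
    sum(state$pool$cargo)
  for (t in 1:60) {
    state <- tick(state, p, cond, g)
    total <- sum(state$field$free) + sum(state$field$bound) +
      sum(state$pool$cargo)
    expect_equal(total, total0, tolerance = 1e-6)
    expect_true(all(state$field$free >= 0) && all(state$field$bound >= 0))
    # per-agent cargo ledger: ingested - released == cargo, all >= 0
    expect_equal(state$pool$ingested - state$pool$released,
                 state$pool$cargo, tolerance = 1e-9)
    expect_true(all(state$pool$cargo >= 0))
  }
})
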