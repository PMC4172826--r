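test_that("patch classification follows radial distance and matches a
           brute-force enumeration", {
  g <- default_grid

  expect_identical(region_of(g, c(4.9, 0)), "nucleus")
  expect_identical(region_of(g, c(5.1, 0)), "cytosol")
  expect_identical(region_of(g, c(0, 15.1)), "exterior")
  expect_identical(region_of(g, c(0, 0)), "nucleus")
  expect_identical(region_of(g, c(10, 0)), "cytosol")
  expect_identical(region_of(g, c(20, 0)), "exterior")

  # independent oracle: enumerate every patch centre directly
  ctr <- -15 + (seq_len(60) - 0.5) * 0.5
  n_cyto <- 0L
  for (cx in ctr) for (cy in ctr) {
    r <- sqrt(cx^2 + cy^2)
    if (r > 5 && r <= 15) n_cyto <- n_cyto + 1L
  }
  expect_identical(sum(g$cytosol), n_cyto)
  # and the count sits within 2% of the continuous annulus area
  expect_lt(abs(n_cyto - pi * (15^2 - 5^2) / 0.25) / (pi * 200 / 0.25), 0.02)

  # degenerate nucleus: every in-cell patch is cytosol
  g0 <- build_grid(30, 0, 0.5)
  expect_false(any(g0$label == "nucleus"))
  expect_identical(sum(g0$cytosol), sum(g0$label != "exterior"))

  # border ring patches are cytosolic with an exterior 8-neighbour
  expect_true(all(g$label[g$border] == "cytosol"))
})

test_that("classification is invariant under 90-degree lattice rotation", {
  g <- default_grid
  rot90 <- function(m) t(m)[, rev(seq_len(ncol(m)))]
  expect_identical(rot90(g$label), g$label)
  expect_identical(rot90(g$cytosol), g$cytosol)
})

test_that("invalid geometries are rejected", {
  expect_error(build_grid(-1, 0, 0.5), "invalid geometry")
  expect_error(build_grid(30, 10, 0), "invalid geometry")
  expect_error(build_grid(10, 12, 0.5), "invalid geometry")
})

test_that("clamp_move stops at the violated boundary and is idempotent", {
  g <- default_grid
  # inward move from radius 6 by 2 um stops on the nuclear envelope
  expect_equal(clamp_move(g, c(6, 0), c(4, 0)), c(5, 0), tolerance = 1e-12)
  # outward move from radius 14 by 2 um stops on the plasma membrane
  expect_equal(clamp_move(g, c(14, 0), c(16, 0)), c(15, 0),
               tolerance = 1e-12)
  # interior move not crossing a boundary is returned unchanged
  expect_identical(clamp_move(g, c(8, 0), c(9.5, 1)), c(9.5, 1))

  # idempotency over random segments
  set.seed(1)
  for (k in 1:200) {
    from <- random_cytosol_position(g, 1)[1, ]
    th <- stats::runif(1, 0, 2 * pi)
    to <- from + 2 * c(cos(th), sin(th))
    p1 <- clamp_move(g, from, to)
    r1 <- sqrt(sum(p1^2))
    expect_true(r1 >= 5 - 1e-9 && r1 <= 15 + 1e-9)
    expect_equal(clamp_move(g, p1, p1), p1, tolerance = 1e-12)
  }
})

test_that("random cytosol positions are area-uniform over the annulus", {
  g <- default_grid
  set.seed(42)
  pos <- random_cytosol_position(g, 1e4)
  r <- sqrt(rowSums(pos^2))
  expect_true(all(r >= 5 & r <= 15))
  # area-weighted mean radius: (2/3)(15^3 - 5^3)/(15^2 - 5^2) = 10.833
  expect_equal(mean(r), (2 / 3) * (15^3 - 5^3) / (15^2 - 5^2),
               tolerance = 0.01)
  # seeded determinism
  set.seed(42)
  expect_identical(random_cytosol_position(g, 1e4), pos)
})
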