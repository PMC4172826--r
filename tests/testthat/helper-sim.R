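# shared fixtures and comparators for the simulation tests

default_grid <- build_grid(30, 10, 0.5)
small_grid <- build_grid(10, 4, 0.5)

# a pool built from explicit per-agent fields (defaults are valid agents)
make_pool <- function(kind, x, y, size = 0.1, birth = 0, mat_time = NA_real_,
                      lifetime = NA_real_, cargo = 0, formed = NA_real_,
                      ingested = cargo, released = 0) {
  n <- length(kind)
  if (is.character(kind)) kind <- unname(agent_kinds[kind])
  p <- empty_pool()
  p$id <- seq_len(n)
  p$kind <- as.integer(kind)
  p$x <- rep_len(x, n); p$y <- rep_len(y, n)
  p$size <- rep_len(size, n)
  p$birth <- rep_len(birth, n)
  p$mat_time <- rep_len(mat_time, n)
  p$lifetime <- rep_len(lifetime, n)
  p$cargo <- rep_len(cargo, n)
  p$formed <- rep_len(formed, n)
  p$ingested <- rep_len(ingested, n)
  p$released <- rep_len(released, n)
  p
}

# strict pool comparison (NA-aware, numeric tolerance)
expect_pool_equal <- function(p1, p2, tol = 1e-9) {
  d1 <- as.data.frame(p1); d2 <- as.data.frame(p2)
  expect_equal(nrow(d1), nrow(d2))
  if (nrow(d1) != nrow(d2)) return(invisible(FALSE))
  for (cl in names(d1)) {
    a <- d1[[cl]]; b <- d2[[cl]]
    if (is.character(a)) {
      expect_identical(a, b)
    } else {
      expect_identical(is.na(a), is.na(b))
      ok <- !is.na(a)
      expect_true(all(abs(a[ok] - b[ok]) <= tol),
                  label = paste("pool column", cl, "within", tol))
    }
  }
  invisible(TRUE)
}

# a random small simulation state for oracle-equivalence checks
random_small_state <- function(seed, variant = c("core", "integrative")) {
  variant <- match.arg(variant)
  set.seed(seed)
  p <- if (variant == "core")
    core_params(initial_pp = 2, initial_ap = 6, initial_ly = 5,
                initial_al = 5)
  else
    integrative_params(initial_pp = 2, initial_ap = 6, initial_ly = 5,
                       initial_al = 5)
  cond <- condition(sample(c("FM", "ND"), 1), baf = stats::runif(1) < 0.5)
  st <- initialize_state(p, cond, small_grid, seed = seed + 1)
  list(state = st, params = p, cond = cond, grid = small_grid)
}

# six-component reference used in fitness tests
ref6 <- c(count_ap = 31, count_ly = 19, count_al = 28,
          size_ap = 0.08, size_ly = 0.10, size_al = 0.30)
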