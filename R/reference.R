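#' Naive reference implementation of one tick
#'
#' A deliberately unoptimised, per-agent / per-patch re-implementation of
#' the tick loop, used as an oracle in the test suite: it follows the same
#' documented sub-step order and RNG draw protocol as [tick()] but computes
#' everything with explicit scalar loops (pairwise distances by hand,
#' patch-by-patch fluxes and diffusion). Given the same state and RNG seed
#' it must reproduce the production tick.
#'
#' Not intended for production use; cost grows quickly with lattice size.
#'
#' @inheritParams tick
#' @return the advanced `sim_state`
#' @export
reference_tick <- function(state, params, cond, grid) {
  if (state$aborted) stop("cannot tick an aborted state")
  pool <- state$pool
  rates <- state$rates
  tnow <- state$tick + 1

  # (1) creation: PP then LY, one spawn at a time
  for (kind in c(.PP, .LY)) {
    lambda <- if (kind == .PP) rates$pp_creation else rates$ly_creation
    n_new <- stats::rpois(1, lambda)
    for (k in seq_len(n_new)) {
      pool <- .pool_bind(pool, spawn_agent(kind, params, grid, tnow,
                                           variant = state$variant,
                                           next_id = state$next_id))
      state$next_id <- state$next_id + 1L
    }
  }

  n <- pool_size(pool)
  # (2) growth
  for (i in seq_len(n)) {
    g <- switch(pool$kind[i], params$pp_growth, params$ap_growth,
                params$ly_growth, params$al_growth)
    pool$size[i] <- pool$size[i] + g
  }
  # (3) maturation
  for (i in seq_len(n)) {
    if (pool$kind[i] == .PP && (tnow - pool$birth[i]) >= pool$mat_time[i]) {
      pool$kind[i] <- .AP
      pool$mat_time[i] <- NA_real_
      pool$cargo[i] <- 0
    }
  }
  # (4) movement: one uniform per agent in pool order
  for (i in seq_len(n)) {
    u <- stats::runif(1)
    sp <- params$movement_speed
    from <- c(pool$x[i], pool$y[i])
    if (pool$kind[i] %in% c(.PP, .AL)) {
      th <- 2 * pi * u
      to <- from + sp * c(cos(th), sin(th))
    } else {
      p_in <- if (pool$kind[i] == .AP) rates$ap_toward_nucleus
      else rates$ly_toward_nucleus
      r <- sqrt(sum(from^2)); if (r == 0) r <- 1
      dirv <- from / r
      to <- if (u < p_in) from - sp * dirv else from + sp * dirv
    }
    to <- clamp_move(grid, from, to)
    pool$x[i] <- to[1]; pool$y[i] <- to[2]
  }
  # (5) fusion: canonical pair list, randomised visiting order
  pairs <- list()
  for (i in seq_len(max(n - 1, 0))) for (j in seq(i + 1, length.out = n - i)) {
    if (pool$kind[i] == .PP || pool$kind[j] == .PP) next
    dd <- sqrt((pool$x[i] - pool$x[j])^2 + (pool$y[i] - pool$y[j])^2)
    if (dd <= params$contact_radius) pairs[[length(pairs) + 1]] <- c(i, j)
  }
  if (length(pairs)) {
    ord <- sample.int(length(pairs))
    used <- logical(n); drop <- logical(n)
    for (k in ord) {
      i <- pairs[[k]][1]; j <- pairs[[k]][2]
      if (used[i] || used[j]) next
      pr <- .fusion_prob(pool$kind[i], pool$kind[j], rates)
      if (pr <= 0) next
      if (stats::runif(1) >= pr) next
      used[i] <- used[j] <- TRUE
      ki <- pool$kind[i]; kj <- pool$kind[j]
      if (ki != .AL && kj != .AL) {
        surv <- i; gone <- j
        pool$kind[surv] <- .AL
        mp <- .project_annulus(grid, (pool$x[i] + pool$x[j]) / 2,
                               (pool$y[i] + pool$y[j]) / 2)
        pool$x[surv] <- mp[1]
        pool$y[surv] <- mp[2]
        pool$formed[surv] <- tnow
        pool$birth[surv] <- tnow
        pool$mat_time[surv] <- NA_real_
        pool$lifetime[surv] <-
          if (identical(rates$variant, "core"))
            .sample_duration(1, rates$al_lifetime_mean,
                             params$lifetime_distribution)
          else NA_real_
      } else if (ki == .AL && kj == .AL) {
        surv <- if (pool$formed[j] < pool$formed[i]) j else i
        gone <- if (surv == i) j else i
      } else {
        surv <- if (ki == .AL) i else j
        gone <- if (surv == i) j else i
      }
      pool$size[surv] <- pool$size[i] + pool$size[j]
      pool$cargo[surv] <- pool$cargo[i] + pool$cargo[j]
      pool$ingested[surv] <- pool$ingested[i] + pool$ingested[j]
      pool$released[surv] <- pool$released[i] + pool$released[j]
      drop[gone] <- TRUE
    }
    if (any(drop)) pool <- .pool_subset(pool, !drop)
  }
  # (6) degradation: death draws in pool order, then per-death processing
  n <- pool_size(pool)
  die <- logical(n)
  al_order <- which(pool$kind == .AL)
  for (i in seq_len(n)) {
    if (pool$kind[i] == .LY) {
      die[i] <- (tnow - pool$birth[i]) > pool$lifetime[i]
    } else if (pool$kind[i] == .AL) {
      if (identical(rates$variant, "core")) {
        die[i] <- (tnow - pool$formed[i]) > pool$lifetime[i]
      }
    }
  }
  if (!identical(rates$variant, "core") && length(al_order)) {
    for (i in al_order) die[i] <- stats::runif(1) < rates$al_degradation
  }
  rel_idx <- integer(); rel_amt <- numeric()
  reformed <- empty_pool()
  for (i in al_order[die[al_order]]) {
    if (pool$cargo[i] > 0) {
      rel_idx <- c(rel_idx, .flux_patch_linear(grid, pool$x[i], pool$y[i]))
      rel_amt <- c(rel_amt, pool$cargo[i])
      pool$released[i] <- pool$released[i] + pool$cargo[i]
      pool$cargo[i] <- 0
    }
    if (stats::runif(1) < rates$reformation) {
      ly <- list(id = state$next_id, kind = .LY,
                 x = pool$x[i], y = pool$y[i],
                 size = params$ly_initial_size, birth = tnow,
                 mat_time = NA_real_,
                 lifetime = .sample_duration(1, params$ly_lifetime_mean,
                                             params$lifetime_distribution),
                 cargo = 0, formed = NA_real_, ingested = 0, released = 0)
      state$next_id <- state$next_id + 1L
      for (f in .pool_fields) reformed[[f]] <- c(reformed[[f]], ly[[f]])
    }
  }
  pool <- .pool_subset(pool, !die)
  pool <- .pool_bind(pool, reformed)

  # (7) nutrient fluxes and diffusion, patch by patch
  if (identical(state$variant, "integrative")) {
    field <- state$field
    for (k in seq_along(rel_idx))
      field$free[rel_idx[k]] <- field$free[rel_idx[k]] + rel_amt[k]
    nn <- grid$n
    for (jj in seq_len(nn)) for (ii in seq_len(nn)) {
      if (!grid$cytosol[ii, jj]) next
      if (grid$border[ii, jj] && cond$uptake_scale > 0)
        field$free[ii, jj] <- field$free[ii, jj] +
          params$border_influx * cond$uptake_scale
    }
    for (jj in seq_len(nn)) for (ii in seq_len(nn)) {
      if (!grid$cytosol[ii, jj]) next
      if (params$decay_pool == "free")
        field$free[ii, jj] <- max(field$free[ii, jj] - params$free_decay, 0)
      else
        field$bound[ii, jj] <- max(field$bound[ii, jj] - params$free_decay, 0)
      conv <- min(params$conversion_rate * cond$metabolism_scale,
                  field$free[ii, jj])
      field$free[ii, jj] <- field$free[ii, jj] - conv
      field$bound[ii, jj] <- field$bound[ii, jj] + conv
    }
    np <- pool_size(pool)
    for (i in seq_len(np)) {
      pi <- .flux_patch_linear(grid, pool$x[i], pool$y[i])
      if (pool$kind[i] == .LY) {
        amt <- min(params$ly_recycling, field$bound[pi])
        field$bound[pi] <- field$bound[pi] - amt
        field$free[pi] <- field$free[pi] + amt
      }
    }
    for (i in seq_len(np)) {
      pi <- .flux_patch_linear(grid, pool$x[i], pool$y[i])
      if (pool$kind[i] == .AP) {
        amt <- min(params$ap_uptake, field$bound[pi])
        field$bound[pi] <- field$bound[pi] - amt
        pool$cargo[i] <- pool$cargo[i] + amt
        pool$ingested[i] <- pool$ingested[i] + amt
      }
    }
    for (i in seq_len(np)) {
      pi <- .flux_patch_linear(grid, pool$x[i], pool$y[i])
      if (pool$kind[i] == .AL) {
        amt <- min(params$al_release, pool$cargo[i])
        pool$cargo[i] <- pool$cargo[i] - amt
        pool$released[i] <- pool$released[i] + amt
        field$free[pi] <- field$free[pi] + amt
      }
    }
    # diffusion: explicit neighbour loops, retained off-cytosol shares
    for (pool_nm in c("free", "bound")) {
      f <- if (pool_nm == "free") params$free_diffusion
      else params$bound_diffusion
      if (f <= 0) next
      A <- field[[pool_nm]]
      B <- matrix(0, nn, nn)
      for (jj in seq_len(nn)) for (ii in seq_len(nn)) {
        if (!grid$cytosol[ii, jj]) next
        share <- f * A[ii, jj] / 8
        kept <- A[ii, jj] - 8 * share
        for (dj in -1:1) for (di in -1:1) {
          if (di == 0 && dj == 0) next
          ti <- ii + di; tj <- jj + dj
          if (ti >= 1 && ti <= nn && tj >= 1 && tj <= nn &&
              grid$cytosol[ti, tj]) {
            B[ti, tj] <- B[ti, tj] + share
          } else {
            kept <- kept + share
          }
        }
        B[ii, jj] <- B[ii, jj] + kept
      }
      field[[pool_nm]] <- B
    }
    state$field <- field
    tot <- 0
    for (jj in seq_len(nn)) for (ii in seq_len(nn))
      if (grid$cytosol[ii, jj]) tot <- tot + field$free[ii, jj]
    state$delta <- max(0, field$baseline - tot / sum(grid$cytosol))
  }
  state$rates <- effective_rates(params, state$delta, cond, state$variant)
  state$pool <- pool
  state$tick <- tnow
  if (pool_size(pool) > params$agent_cap) {
    state$aborted <- TRUE
    state$abort_reason <- "agent cap exceeded"
  } else if (identical(state$variant, "integrative") &&
             sum(state$field$free) <= 0) {
    state$aborted <- TRUE
    state$abort_reason <- "nutrients exhausted"
  }
  state
}
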