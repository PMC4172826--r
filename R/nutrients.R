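#' Initialise the nutrient field
#'
#' The integrative model tracks two per-patch pools on the cytosolic
#' lattice: \emph{free} nutrients (amino-acid-like building blocks, not an
#' autophagy substrate) and \emph{bound} nutrients (macromolecules that
#' autophagosomes can ingest). Every cytosol patch starts at
#' `params$free_init` / `params$bound_init` (default 20/20); patches outside
#' the cytosol carry no nutrients.
#'
#' @param grid a `grid_spec`
#' @param params a `model_params`
#' @return an object of class `nutrient_field`: list with `free` and
#'   `bound` (n x n matrices), the `cytosol` mask, `baseline` (the
#'   initialisation mean of free nutrients) and lattice size `n`
#' @export
init_field <- function(grid, params) {
  free <- matrix(0, grid$n, grid$n)
  bound <- matrix(0, grid$n, grid$n)
  free[grid$cytosol] <- params$free_init
  bound[grid$cytosol] <- params$bound_init
  structure(list(free = free, bound = bound, cytosol = grid$cytosol,
                 cyto_idx = grid$cyto_idx, baseline = params$free_init,
                 n = grid$n),
            class = "nutrient_field")
}

#' @export
print.nutrient_field <- function(x, ...) {
  nc <- sum(x$cytosol)
  cat(sprintf(
    "<nutrient_field> %d cytosol patches; mean free %.3f, mean bound %.3f\n",
    nc, sum(x$free) / nc, sum(x$bound) / nc))
  invisible(x)
}

#' Apply one tick of nutrient fluxes
#'
#' In fixed order: (1) boundary influx -- every cytosol-border patch gains
#' `border_influx * condition$uptake_scale` free nutrients (1.1/min under
#' FM; 0 under ND); (2) global decay -- every cytosol patch loses up to
#' `free_decay` (0.05/min) from the configured pool (free by default);
#' (3) anabolic conversion -- up to
#' `conversion_rate * condition$metabolism_scale` (0.045/min) moves free to
#' bound per patch; (4) lysosomal recycling -- each LY moves up to
#' `ly_recycling` (1.5/min) bound to free on its patch; (5) autophagosomal
#' uptake -- each AP ingests up to `ap_uptake` (2.25/min) bound from its
#' patch into its cargo; (6) autolysosomal release -- each AL releases up to
#' `al_release` (2.25/min) of its cargo as free nutrients on its patch.
#' Every flux is capped by availability, so both pools stay non-negative.
#' Agent-mediated fluxes are processed in pool order (co-located agents
#' compete sequentially for the same patch).
#'
#' @param field a `nutrient_field`
#' @param pool an `agent_pool`
#' @param params a `model_params`
#' @param cond a `sim_condition`
#' @param grid a `grid_spec`
#' @return a list with the updated `field` and `pool` (AP cargo and AL
#'   release ledgers change here)
#' @export
apply_fluxes <- function(field, pool, params, cond, grid) {
  free <- field$free
  bound <- field$bound
  cyt <- grid$cyto_idx

  # (1) boundary influx of free nutrients
  if (cond$uptake_scale > 0)
    free[grid$border] <- free[grid$border] +
      params$border_influx * cond$uptake_scale

  # (2) global decay, capped at zero
  if (params$decay_pool == "free") {
    free[cyt] <- pmax(free[cyt] - params$free_decay, 0)
  } else {
    bound[cyt] <- pmax(bound[cyt] - params$free_decay, 0)
  }

  # (3) free -> bound conversion (anabolism)
  conv <- pmin(params$conversion_rate * cond$metabolism_scale, free[cyt])
  free[cyt] <- free[cyt] - conv
  bound[cyt] <- bound[cyt] + conv

  if (pool_size(pool) > 0) {
    pidx <- .flux_patch_vec(grid, pool$x, pool$y)
    kind <- pool$kind
    # (4) lysosomal recycling bound -> free
    r_ly <- params$ly_recycling
    for (i in which(kind == .LY)) {
      amt <- min(r_ly, bound[pidx[i]])
      bound[pidx[i]] <- bound[pidx[i]] - amt
      free[pidx[i]] <- free[pidx[i]] + amt
    }
    # (5) autophagosomal uptake bound -> cargo
    r_ap <- params$ap_uptake
    for (i in which(kind == .AP)) {
      amt <- min(r_ap, bound[pidx[i]])
      bound[pidx[i]] <- bound[pidx[i]] - amt
      pool$cargo[i] <- pool$cargo[i] + amt
      pool$ingested[i] <- pool$ingested[i] + amt
    }
    # (6) autolysosomal release cargo -> free
    r_al <- params$al_release
    for (i in which(kind == .AL)) {
      amt <- min(r_al, pool$cargo[i])
      pool$cargo[i] <- pool$cargo[i] - amt
      pool$released[i] <- pool$released[i] + amt
      free[pidx[i]] <- free[pidx[i]] + amt
    }
  }
  field$free <- free
  field$bound <- bound
  list(field = field, pool = pool)
}

#' Diffuse the nutrient pools
#'
#' Each cytosol patch gives away a fraction of its content
#' (`free_diffusion` 70%, `bound_diffusion` 50%) split into eight equal
#' shares, one per 8-neighbour. Shares directed at non-cytosol neighbours
#' (nucleus, exterior, off-lattice) are retained by the source patch, so
#' each pool's total mass is conserved exactly.
#'
#' @param field a `nutrient_field`
#' @param params a `model_params`
#' @param grid a `grid_spec`
#' @return the diffused `nutrient_field`
#' @export
diffuse <- function(field, params, grid) {
  n <- grid$n
  i1 <- 1:n; i2 <- 2:(n + 1); i3 <- 3:(n + 2)
  for (pool_nm in c("free", "bound")) {
    f <- if (pool_nm == "free") params$free_diffusion else
      params$bound_diffusion
    if (f <= 0) next
    A <- field[[pool_nm]]
    P <- matrix(0, n + 2, n + 2)       # zero-padded share matrix
    P[i2, i2] <- (f / 8) * A
    inflow <- P[i1, i1] + P[i1, i2] + P[i1, i3] +
      P[i2, i1] + P[i2, i3] +
      P[i3, i1] + P[i3, i2] + P[i3, i3]
    # each patch sends one share per cytosolic neighbour, receives the
    # shares addressed to it (cytosol patches only hold nutrients)
    field[[pool_nm]] <- A - (f / 8) * A * grid$neigh_count +
      inflow * grid$cytosol
  }
  field
}

#' Free-nutrient deficit relative to baseline
#'
#' The nutrient-coupling signal of the integrative model: the shortfall of
#' the current mean free nutrients per cytosol patch below the
#' initialisation baseline (default 20), floored at zero. Zero at
#' initialisation and whenever the cell is replete.
#'
#' @param field a `nutrient_field`
#' @return non-negative scalar deficit (nutrient units per patch)
#' @export
delta_nutrition <- function(field) {
  idx <- if (is.null(field$cyto_idx)) which(field$cytosol) else field$cyto_idx
  m <- sum(field$free[idx]) / length(idx)
  max(0, field$baseline - m)
}
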