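#' @name agents
#' @title Vesicle agents and their per-tick behaviours
#'
#' @description
#' Agents are the four vesicle species of the autophagy pathway: phagophores
#' (`PP`), autophagosomes (`AP`), lysosomes (`LY`) and autolysosomes (`AL`).
#' A pool of agents is held as a list of parallel vectors (class
#' `agent_pool`) with one entry per vesicle:
#' \describe{
#'   \item{id}{stable integer identifier}
#'   \item{kind}{integer code 1..4 = PP, AP, LY, AL (see [agent_kinds])}
#'   \item{x, y}{position in um, centre-origin}
#'   \item{size}{membrane area in um^2}
#'   \item{birth}{tick of creation (or of the last kind change for LY/AL)}
#'   \item{mat_time}{PP only: sampled maturation duration (min)}
#'   \item{lifetime}{LY, and AL in the core variant: sampled lifetime (min)}
#'   \item{cargo}{AP/AL only: bound nutrients ingested and not yet released}
#'   \item{formed}{AL only: tick at which the vesicle became an AL}
#'   \item{ingested, released}{cumulative cargo ledger; the invariant
#'     `ingested - released == cargo` holds for every agent at all times}
#' }
#'
#' All stochastic steps consume draws from the session RNG in a fixed,
#' documented order (pool order within each phase), so that a naive
#' per-agent reference implementation reproduces the production tick
#' exactly under the same seed.
NULL

#' Agent kind codes
#'
#' Integer codes used in the `kind` column of an agent pool, in pathway
#' order: phagophore, autophagosome, lysosome, autolysosome.
#' @export
agent_kinds <- c(PP = 1L, AP = 2L, LY = 3L, AL = 4L)

.PP <- 1L; .AP <- 2L; .LY <- 3L; .AL <- 4L

.pool_fields <- c("id", "kind", "x", "y", "size", "birth", "mat_time",
                  "lifetime", "cargo", "formed", "ingested", "released")

#' Create an empty agent pool
#' @return an `agent_pool` with zero agents
#' @export
empty_pool <- function() {
  structure(list(
    id = integer(), kind = integer(), x = numeric(), y = numeric(),
    size = numeric(), birth = numeric(), mat_time = numeric(),
    lifetime = numeric(), cargo = numeric(), formed = numeric(),
    ingested = numeric(), released = numeric()
  ), class = "agent_pool")
}

#' @export
print.agent_pool <- function(x, ...) {
  tab <- tabulate(x$kind, 4)
  cat(sprintf("<agent_pool> %d agents (PP %d, AP %d, LY %d, AL %d)\n",
              length(x$id), tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' @export
as.data.frame.agent_pool <- function(x, ...) {
  data.frame(id = x$id, kind = names(agent_kinds)[x$kind], x = x$x, y = x$y,
             size = x$size, birth = x$birth, mat_time = x$mat_time,
             lifetime = x$lifetime, cargo = x$cargo, formed = x$formed,
             ingested = x$ingested, released = x$released)
}

#' Number of agents in a pool
#' @param pool an `agent_pool`
#' @export
pool_size <- function(pool) length(pool$id)

# row-bind two pools
.pool_bind <- function(a, b) {
  if (pool_size(b) == 0) return(a)
  for (f in .pool_fields) a[[f]] <- c(a[[f]], b[[f]])
  a
}

# subset a pool by index/logical
.pool_subset <- function(pool, keep) {
  for (f in .pool_fields) pool[[f]] <- pool[[f]][keep]
  pool
}

# sampled duration: exponential with the stated mean (default) or the mean
# itself in "fixed" mode; a zero mean yields zero
.sample_duration <- function(n, mean, dist) {
  if (n == 0) return(numeric())
  if (dist == "fixed") return(rep(mean, n))
  if (mean <= 0) return(rep(0, n))
  stats::rexp(n, rate = 1 / mean)
}

#' Spawn new agents
#'
#' Creates `n` agents of one kind at uniform cytosolic positions with the
#' kind's initial size. PPs sample a maturation time and LYs a lifetime
#' (exponential with the configured means by default). ALs (t = 0
#' initialisation only) sample a lifetime in the core variant; APs at t = 0
#' take size `pp_initial_size + pp_growth *` (a sampled maturation age),
#' consistent with the phagophore-to-autophagosome pipeline at steady state.
#'
#' RNG draw order per agent: position (2 uniforms), then the kind's duration
#' or age draw if any.
#'
#' @param kind one of `"PP"`, `"AP"`, `"LY"`, `"AL"` (or an integer code)
#' @param params a `model_params`
#' @param grid a `grid_spec`
#' @param tick current time (min)
#' @param n number of agents to spawn
#' @param variant `"core"` or `"integrative"` (controls AL lifetime sampling)
#' @param al_lifetime_mean effective mean AL lifetime (min); defaults to the
#'   parameter value, callers apply the BAF attenuation
#' @param next_id first id to assign
#' @return an `agent_pool` of `n` agents
#' @export
spawn_agent <- function(kind, params, grid, tick, n = 1,
                        variant = attr(params, "variant"),
                        al_lifetime_mean = params$al_lifetime_mean,
                        next_id = 1L) {
  if (is.character(kind)) kind <- agent_kinds[[kind]]
  if (!kind %in% 1:4) stop("unknown agent kind")
  pool <- empty_pool()
  if (n == 0) return(pool)
  pool$id <- next_id + seq_len(n) - 1L
  pool$kind <- rep(as.integer(kind), n)
  pool$x <- numeric(n); pool$y <- numeric(n)
  pool$size <- numeric(n)
  pool$birth <- rep(as.numeric(tick), n)
  pool$mat_time <- rep(NA_real_, n)
  pool$lifetime <- rep(NA_real_, n)
  pool$cargo <- numeric(n)
  pool$formed <- rep(NA_real_, n)
  pool$ingested <- numeric(n)
  pool$released <- numeric(n)
  # one agent at a time keeps the per-agent draw order explicit:
  # position (2 uniforms), then the kind's duration/age draw
  for (k in seq_len(n)) {
    pos <- random_cytosol_position(grid, 1)
    pool$x[k] <- pos[1, 1]; pool$y[k] <- pos[1, 2]
    if (kind == .PP) {
      pool$size[k] <- params$pp_initial_size
      pool$mat_time[k] <- .sample_duration(1, params$pp_maturation_mean,
                                           params$lifetime_distribution)
    } else if (kind == .AP) {
      age <- .sample_duration(1, params$pp_maturation_mean,
                              params$lifetime_distribution)
      pool$size[k] <- params$pp_initial_size + params$pp_growth * age
    } else if (kind == .LY) {
      pool$size[k] <- params$ly_initial_size
      pool$lifetime[k] <- .sample_duration(1, params$ly_lifetime_mean,
                                           params$lifetime_distribution)
    } else {
      pool$size[k] <- params$al_initial_size
      pool$formed[k] <- tick
      if (identical(variant, "core"))
        pool$lifetime[k] <- .sample_duration(1, al_lifetime_mean,
                                             params$lifetime_distribution)
    }
  }
  pool
}

# vectorised boundary clamp for a batch of proposed moves; the segment
# leaves the annulus through at most one boundary (step << annulus width)
.clamp_vec <- function(grid, fx, fy, tx, ty) {
  r2 <- tx^2 + ty^2
  out <- which(r2 > grid$r_cell^2)
  inn <- if (grid$r_nuc > 0) which(r2 < grid$r_nuc^2) else integer()
  fix <- function(idx, radius, outward) {
    dx <- tx[idx] - fx[idx]; dy <- ty[idx] - fy[idx]
    a <- dx^2 + dy^2
    b <- 2 * (fx[idx] * dx + fy[idx] * dy)
    cc <- fx[idx]^2 + fy[idx]^2 - radius^2
    disc <- pmax(b^2 - 4 * a * cc, 0)
    # from inside going out: larger root; from outside going in: smaller
    t <- if (outward) (-b + sqrt(disc)) / (2 * a)
    else (-b - sqrt(disc)) / (2 * a)
    t[!is.finite(t)] <- 0
    t <- pmin(pmax(t, 0), 1)
    px <- fx[idx] + t * dx; py <- fy[idx] + t * dy
    r <- sqrt(px^2 + py^2)
    s <- ifelse(r > 0, radius / r, 1)
    tx[idx] <<- px * s; ty[idx] <<- py * s
  }
  if (length(out)) fix(out, grid$r_cell, TRUE)
  if (length(inn)) fix(inn, grid$r_nuc, FALSE)
  cbind(tx, ty)
}

#' Move every agent one tick
#'
#' Phagophores and autolysosomes take a 2 um step in a uniformly random
#' direction. Autophagosomes and lysosomes move 2 um radially: inward
#' (towards the nucleus) with probability `rates$ap_toward_nucleus` /
#' `rates$ly_toward_nucleus`, outward otherwise, mimicking bidirectional
#' microtubule transport. Steps are clamped at the nuclear envelope and the
#' plasma membrane. Speed is size-independent.
#'
#' One uniform draw per agent, in pool order: PP/AL use it as the angle,
#' AP/LY as the inward/outward Bernoulli.
#'
#' @param pool an `agent_pool`
#' @param rates an `effective_rates` list (see [effective_rates()])
#' @param params a `model_params`
#' @param grid a `grid_spec`
#' @return the moved pool
#' @export
step_movement <- function(pool, rates, params, grid) {
  n <- pool_size(pool)
  if (n == 0) return(pool)
  u <- stats::runif(n)
  sp <- params$movement_speed
  kind <- pool$kind
  dx <- numeric(n); dy <- numeric(n)

  rnd <- kind == .PP | kind == .AL
  th <- 2 * pi * u[rnd]
  dx[rnd] <- sp * cos(th); dy[rnd] <- sp * sin(th)

  rad <- !rnd
  if (any(rad)) {
    p_in <- ifelse(kind[rad] == .AP, rates$ap_toward_nucleus,
                   rates$ly_toward_nucleus)
    sgn <- ifelse(u[rad] < p_in, -1, 1)
    r <- sqrt(pool$x[rad]^2 + pool$y[rad]^2)
    r[r == 0] <- 1
    dx[rad] <- sgn * sp * pool$x[rad] / r
    dy[rad] <- sgn * sp * pool$y[rad] / r
  }
  newp <- .clamp_vec(grid, pool$x, pool$y, pool$x + dx, pool$y + dy)
  pool$x <- unname(newp[, 1]); pool$y <- unname(newp[, 2])
  pool
}

#' Grow every agent by one tick
#'
#' Adds the kind's growth rate (um^2 per min) to each vesicle's area.
#' Deterministic.
#' @inheritParams step_movement
#' @export
step_growth <- function(pool, params) {
  g <- c(params$pp_growth, params$ap_growth, params$ly_growth,
         params$al_growth)
  pool$size <- pool$size + g[pool$kind]
  pool
}

#' Mature phagophores into autophagosomes
#'
#' A PP whose age (`tick - birth`) has reached its sampled maturation time
#' is re-kinded AP, size preserved, cargo ledger initialised to zero.
#' Deterministic given the sampled maturation times.
#' @inheritParams step_movement
#' @param tick current time (min)
#' @export
maturation_check <- function(pool, tick) {
  mat <- pool$kind == .PP & (tick - pool$birth) >= pool$mat_time
  if (any(mat)) {
    pool$kind[mat] <- .AP
    pool$mat_time[mat] <- NA_real_
    pool$cargo[mat] <- 0
  }
  pool
}

# fusion outcome table; only these unordered kind pairs can fuse
.fusion_prob <- function(k1, k2, rates) {
  ks <- sort(c(k1, k2))
  if (ks[1] == .AP && ks[2] == .LY) return(rates$ap_ly_fusion)
  if (ks[2] == .AL && ks[1] %in% c(.AP, .LY)) return(rates$fusion_nonAL_AL)
  if (ks[1] == .AL && ks[2] == .AL) return(rates$fusion_AL_AL)
  0
}

#' Resolve fusion events for one tick
#'
#' Candidate pairs are agents within `contact_radius` (one patch width,
#' 0.5 um) of each other whose kinds can fuse: AP+LY forms a new AL
#' (probability `ap_ly_fusion`, default 1 -- the pathway's defining step);
#' AP+AL and LY+AL are absorbed by the AL (`fusion_nonAL_AL`, 45%); AL+AL
#' merge (`fusion_AL_AL`, 15% core / 30% integrative), the earlier-formed AL
#' surviving. Sizes add exactly; cargo and ledgers add. Each agent fuses at
#' most once per tick; candidate pairs are visited in randomised order to
#' avoid positional bias.
#'
#' RNG order: one `sample.int` over the candidate pairs, then, for each
#' visited pair whose partners are both still free, one uniform; a newly
#' formed AL samples its lifetime (core variant) immediately.
#'
#' @inheritParams step_movement
#' @param tick current time (min)
#' @param grid a `grid_spec` (the new AL of an AP+LY fusion forms at the
#'   partners' midpoint, projected back into the cytosolic annulus)
#' @return the pool after fusions
#' @export
resolve_fusions <- function(pool, rates, params, tick, grid) {
  n <- pool_size(pool)
  if (n < 2) return(pool)
  can <- pool$kind != .PP
  idx <- which(can)
  if (length(idx) < 2) return(pool)

  # candidate pairs within contact range, canonical (i < j) order
  cr <- params$contact_radius
  xs <- pool$x[idx]; ys <- pool$y[idx]
  d <- as.matrix(stats::dist(cbind(xs, ys)))
  hit <- which(upper.tri(d) & d <= cr, arr.ind = TRUE)
  if (nrow(hit) == 0) return(pool)
  pi1 <- idx[hit[, 1]]; pi2 <- idx[hit[, 2]]
  o <- order(pmin(pi1, pi2), pmax(pi1, pi2))
  pi1 <- pi1[o]; pi2 <- pi2[o]

  ord <- sample.int(length(pi1))
  used <- logical(n)
  drop <- logical(n)
  for (k in ord) {
    i <- pi1[k]; j <- pi2[k]
    if (used[i] || used[j]) next
    pr <- .fusion_prob(pool$kind[i], pool$kind[j], rates)
    if (pr <= 0) next
    u <- stats::runif(1)
    if (u >= pr) next
    used[i] <- used[j] <- TRUE
    ki <- pool$kind[i]; kj <- pool$kind[j]
    if (ki != .AL && kj != .AL) {
      # AP + LY -> new AL at the midpoint of the partners
      surv <- i; gone <- j
      pool$kind[surv] <- .AL
      mp <- .project_annulus(grid, (pool$x[i] + pool$x[j]) / 2,
                             (pool$y[i] + pool$y[j]) / 2)
      pool$x[surv] <- mp[1]
      pool$y[surv] <- mp[2]
      pool$formed[surv] <- tick
      pool$birth[surv] <- tick
      pool$mat_time[surv] <- NA_real_
      pool$lifetime[surv] <-
        if (identical(rates$variant, "core"))
          .sample_duration(1, rates$al_lifetime_mean,
                           params$lifetime_distribution)
        else NA_real_
    } else if (ki == .AL && kj == .AL) {
      # survivor = earlier-formed AL (ties: lower index); no rejuvenation
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
  if (any(drop)) pool <- .pool_subset(pool, !drop) else pool
  pool
}

#' Degrade lysosomes and autolysosomes for one tick
#'
#' Lysosomes die when their age exceeds their sampled lifetime. Autolysosome
#' death depends on the model variant: in the core model when the age since
#' formation exceeds the lifetime sampled at formation; in the integrative
#' model as a per-tick Bernoulli with probability `rates$al_degradation`.
#' A dying AL releases its remaining cargo as free nutrients on its patch
#' and, with probability `rates$reformation` (50%), is reformed into a fresh
#' lysosome (initial LY size, new sampled lifetime) at its position
#' (autolysosomal reformation).
#'
#' RNG order: in the integrative variant one uniform per AL in pool order;
#' then, for each dying AL in pool order, one uniform (reformation) and, if
#' reformed, one lifetime draw.
#'
#' @inheritParams step_movement
#' @param tick current time (min)
#' @param next_id id to assign to the first reformed lysosome
#' @return a list with elements `pool` (survivors plus reformed lysosomes),
#'   `released_idx`/`released_amt` (linear patch indices and free-nutrient
#'   amounts released by dying ALs), and `next_id`
#' @export
degradation_step <- function(pool, rates, params, grid, tick, next_id) {
  n <- pool_size(pool)
  if (n == 0)
    return(list(pool = pool, released_idx = integer(),
                released_amt = numeric(), next_id = next_id))

  die <- logical(n)
  isly <- pool$kind == .LY
  die[isly] <- (tick - pool$birth[isly]) > pool$lifetime[isly]
  als <- which(pool$kind == .AL)
  if (identical(rates$variant, "core")) {
    die[als] <- (tick - pool$formed[als]) > pool$lifetime[als]
  } else if (length(als)) {
    u <- stats::runif(length(als))
    die[als] <- u < rates$al_degradation
  }

  dying_al <- als[die[als]]
  nd <- length(dying_al)
  released_idx <- integer(nd); released_amt <- numeric(nd)
  ref_from <- integer(nd); ref_life <- numeric(nd)
  n_rel <- 0L; n_ref <- 0L
  for (i in dying_al) {
    if (pool$cargo[i] > 0) {
      n_rel <- n_rel + 1L
      released_idx[n_rel] <- .flux_patch_linear(grid, pool$x[i], pool$y[i])
      released_amt[n_rel] <- pool$cargo[i]
      pool$released[i] <- pool$released[i] + pool$cargo[i]
      pool$cargo[i] <- 0
    }
    if (stats::runif(1) < rates$reformation) {
      n_ref <- n_ref + 1L
      ref_from[n_ref] <- i
      ref_life[n_ref] <- .sample_duration(1, params$ly_lifetime_mean,
                                          params$lifetime_distribution)
    }
  }
  reformed <- empty_pool()
  if (n_ref > 0) {
    src <- ref_from[seq_len(n_ref)]
    reformed$id <- next_id + seq_len(n_ref) - 1L
    reformed$kind <- rep(.LY, n_ref)
    reformed$x <- pool$x[src]; reformed$y <- pool$y[src]
    reformed$size <- rep(params$ly_initial_size, n_ref)
    reformed$birth <- rep(as.numeric(tick), n_ref)
    reformed$mat_time <- rep(NA_real_, n_ref)
    reformed$lifetime <- ref_life[seq_len(n_ref)]
    reformed$cargo <- numeric(n_ref)
    reformed$formed <- rep(NA_real_, n_ref)
    reformed$ingested <- numeric(n_ref)
    reformed$released <- numeric(n_ref)
    next_id <- next_id + n_ref
  }
  pool <- .pool_subset(pool, !die)
  pool <- .pool_bind(pool, reformed)
  list(pool = pool, released_idx = released_idx[seq_len(n_rel)],
       released_amt = released_amt[seq_len(n_rel)], next_id = next_id)
}
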