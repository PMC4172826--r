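#' Fitness of a model summary against reference data
#'
#' The calibration objective: the sum over the six compared components --
#' count and mean size of autophagosomes, lysosomes and autolysosomes -- of
#' the squared percent deviation `((model/reference - 1) * 100)^2`. An
#' exact match scores 0; a single 10% deviation scores 100; two 10%
#' deviations score 200; a single 20% deviation scores 400, so several
#' small deviations are preferred over one large one.
#'
#' @param summary named numeric of 6 model values (`count_ap`, `count_ly`,
#'   `count_al`, `size_ap`, `size_ly`, `size_al`)
#' @param reference named numeric of the 6 corresponding reference values,
#'   all strictly positive
#' @return a list of class `fitness_result`: `fitness` (the score),
#'   `deviations` (per-component percent deviations), `components` (their
#'   squares), `n_aborted` (0 here) and `penalty_applied` (0 here)
#' @export
fitness <- function(summary, reference) {
  comp <- c("count_ap", "count_ly", "count_al",
            "size_ap", "size_ly", "size_al")
  if (!all(comp %in% names(reference)) || !all(comp %in% names(summary)))
    stop("summary and reference need components: ",
         paste(comp, collapse = ", "))
  reference <- reference[comp]; summary <- summary[comp]
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference entries must be finite and > 0 (ratios must be defined)")
  dev <- (summary / reference - 1) * 100
  structure(list(
    fitness = sum(dev^2), deviations = dev, components = dev^2,
    n_aborted = 0L, penalty_applied = 0
  ), class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("<fitness_result> fitness %.4g (penalty %.4g, %d aborted)\n",
              x$fitness, x$penalty_applied, x$n_aborted))
  invisible(x)
}

#' Evaluate a parameter set against reference data
#'
#' Runs an ensemble per condition, computes the fitness on the across-run
#' mean summary of the completed runs, and adds an abort penalty of
#' `penalty` (default 100000) for every aborted run (cap exceeded or
#' nutrients exhausted). Multi-condition evaluation (e.g. FM with and
#' without BAF, fit simultaneously) sums the per-condition fitness.
#'
#' @param params a `model_params`
#' @param conds a `sim_condition` or list of them
#' @param references a named 6-vector or list of them (one per condition)
#' @param n_runs runs per condition
#' @param duration,readout run length and readout tick (min)
#' @param seed master seed (condition `k` uses `seed + (k-1) * n_runs`)
#' @param penalty additive penalty per aborted run
#' @param grid a `grid_spec`
#' @return a `fitness_result`; if every run aborts, the result carries only
#'   penalties and `all_aborted = TRUE`
#' @export
evaluate_params <- function(params, conds, references, n_runs = 100,
                            duration = 180, readout = duration, seed = 1,
                            penalty = 1e5, grid = build_grid()) {
  if (inherits(conds, "sim_condition")) conds <- list(conds)
  if (!is.list(references) || !is.null(names(references)))
    references <- list(references)
  if (length(conds) != length(references))
    stop("need one reference per condition")
  total <- 0; n_ab <- 0L; devs <- list(); all_ab <- TRUE
  for (k in seq_along(conds)) {
    ens <- run_ensemble(params, conds[[k]], n_runs = n_runs,
                        duration = duration, readout = readout,
                        seed = seed + (k - 1) * n_runs, grid = grid)
    n_ab <- n_ab + ens$n_aborted
    if (ens$n_aborted < n_runs) {
      all_ab <- FALSE
      fr <- fitness(ens$mean, references[[k]])
      total <- total + fr$fitness
      devs[[k]] <- fr$deviations
    }
  }
  structure(list(
    fitness = total + penalty * n_ab,
    deviations = devs, components = NULL,
    n_aborted = n_ab, penalty_applied = penalty * n_ab,
    all_aborted = all_ab
  ), class = "fitness_result")
}

#' Parameter search space
#'
#' Per-parameter bounds for calibration. Parameters not listed stay fixed
#' at their values in the template set (masking, used e.g. for the
#' two-stage fitting strategy of the integrative model).
#'
#' @param lower,upper named numeric vectors with identical names: bounds
#'   for the free parameters (names must be `model_params` entries)
#' @return a list of class `search_space`
#' @export
search_space <- function(lower, upper) {
  if (!identical(names(lower), names(upper)) || is.null(names(lower)))
    stop("lower and upper must share the same parameter names")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper")
  structure(list(names = names(lower), lower = lower, upper = upper),
            class = "search_space")
}

# instantiate a parameter set from a vector in the space
.space_params <- function(space, x, template) {
  template[space$names] <- as.list(pmin(pmax(x, space$lower), space$upper))
  validate_params(template)
}

#' Fitness of random parameter sets
#'
#' Draws `n_sets` parameter vectors uniformly within the search-space
#' bounds, evaluates each, and summarises the fitness distribution -- the
#' random baseline against which a calibrated set is compared.
#'
#' @param space a `search_space`
#' @param template a `model_params` providing the fixed parameters
#' @param conds,references,n_runs,duration,readout,grid as in
#'   [evaluate_params()]
#' @param n_sets number of random sets (paper-scale default 200)
#' @param seed master seed
#' @return a list: `fitness` (vector of length `n_sets`), `mean`, `min`,
#'   `sets` (matrix of sampled vectors)
#' @export
random_baseline <- function(space, template, conds, references,
                            n_sets = 200, n_runs = 100, duration = 180,
                            readout = duration, seed = 1,
                            grid = build_grid()) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  d <- length(space$names)
  set.seed(seed)
  sets <- matrix(stats::runif(n_sets * d), n_sets, d)
  sets <- sweep(sets, 2, space$upper - space$lower, `*`)
  sets <- sweep(sets, 2, space$lower, `+`)
  colnames(sets) <- space$names
  fit <- numeric(n_sets)
  for (s in seq_len(n_sets)) {
    p <- .space_params(space, sets[s, ], template)
    fit[s] <- evaluate_params(p, conds, references, n_runs = n_runs,
                              duration = duration, readout = readout,
                              seed = seed + s * 1000L, grid = grid)$fitness
  }
  list(fitness = fit, mean = mean(fit), min = min(fit), sets = sets)
}

#' Genetic-algorithm configuration
#'
#' @param pop_size population size
#' @param generations number of generations
#' @param crossover_rate probability a child is produced by blend
#'   crossover rather than cloning a parent
#' @param mutation_rate per-gene probability of Gaussian mutation
#' @param mutation_sd mutation SD as a fraction of each parameter's range
#' @param elitism number of best individuals copied unchanged
#' @param tournament tournament size for selection
#' @param blend_alpha BLX-alpha expansion of the crossover interval
#' @param seed RNG seed for the whole fit
#' @export
ga_config <- function(pop_size = 50, generations = 40,
                      crossover_rate = 0.8, mutation_rate = 0.2,
                      mutation_sd = 0.1, elitism = 2, tournament = 3,
                      blend_alpha = 0.5, seed = 1) {
  structure(list(pop_size = pop_size, generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 elitism = elitism, tournament = tournament,
                 blend_alpha = blend_alpha, seed = seed),
            class = "ga_config")
}

#' Calibrate parameters with a real-valued genetic algorithm
#'
#' Minimises [evaluate_params()] over the free parameters of a search
#' space: tournament selection, BLX-alpha blend crossover, Gaussian
#' mutation (SD a fixed fraction of each parameter's range), and elitism.
#' Each individual is evaluated on its own ensemble; the per-individual
#' evaluation seed is derived from the GA seed, generation and index.
#'
#' @param space a `search_space`
#' @param template a `model_params` providing fixed parameters
#' @param conds,references,n_runs,duration,readout,grid as in
#'   [evaluate_params()]
#' @param ga a `ga_config`
#' @return a list: `best_params` (a `model_params`), `best_vector`,
#'   `best_fitness`, `trace` (data frame of per-generation best/mean
#'   fitness), `population`, `fitness`
#' @export
fit_ga <- function(space, template, conds, references, ga = ga_config(),
                   n_runs = 100, duration = 180, readout = duration,
                   grid = build_grid()) {
  d <- length(space$names)
  rng <- space$upper - space$lower
  set.seed(ga$seed)
  pop <- matrix(stats::runif(ga$pop_size * d), ga$pop_size, d)
  pop <- sweep(sweep(pop, 2, rng, `*`), 2, space$lower, `+`)

  eval_one <- function(x, gen, idx) {
    p <- .space_params(space, x, template)
    evaluate_params(p, conds, references, n_runs = n_runs,
                    duration = duration, readout = readout,
                    seed = (ga$seed * 97L + gen * 1009L + idx * 31L) %%
                      .Machine$integer.max,
                    grid = grid)$fitness
  }

  fit <- vapply(seq_len(ga$pop_size), function(i)
    eval_one(pop[i, ], 0L, i), numeric(1))
  best_fit <- min(fit)
  best_vec <- pop[which.min(fit), ]
  trace <- data.frame(generation = 0, best = best_fit, mean = mean(fit))

  for (gen in seq_len(ga$generations)) {
    ord <- order(fit)
    newpop <- matrix(NA_real_, ga$pop_size, d)
    n_el <- min(ga$elitism, ga$pop_size)
    newpop[seq_len(n_el), ] <- pop[ord[seq_len(n_el)], , drop = FALSE]
    for (i in seq(n_el + 1, length.out = ga$pop_size - n_el)) {
      pick <- function() {
        cand <- sample.int(ga$pop_size, ga$tournament, replace = TRUE)
        cand[which.min(fit[cand])]
      }
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      child <- if (stats::runif(1) < ga$crossover_rate) {
        lo <- pmin(pa, pb); hi <- pmax(pa, pb)
        span <- hi - lo
        stats::runif(d, lo - ga$blend_alpha * span,
                     hi + ga$blend_alpha * span)
      } else pa
      mut <- stats::runif(d) < ga$mutation_rate
      if (any(mut))
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, ga$mutation_sd * rng[mut])
      newpop[i, ] <- pmin(pmax(child, space$lower), space$upper)
    }
    pop <- newpop
    fit <- vapply(seq_len(ga$pop_size), function(i)
      eval_one(pop[i, ], gen, i), numeric(1))
    # elitism guarantee against evaluation noise: if the generation lost
    # the incumbent, reinsert it (vector and recorded fitness) at the worst
    if (min(fit) > best_fit) {
      w <- which.max(fit)
      pop[w, ] <- best_vec
      fit[w] <- best_fit
    } else {
      best_fit <- min(fit)
      best_vec <- pop[which.min(fit), ]
    }
    trace <- rbind(trace, data.frame(generation = gen, best = best_fit,
                                     mean = mean(fit)))
  }
  bv <- stats::setNames(best_vec, space$names)
  list(best_params = .space_params(space, bv, template),
       best_vector = bv, best_fitness = best_fit, trace = trace,
       population = pop, fitness = fit)
}

#' Synthetic reference data from known parameters
#'
#' Generates a six-component reference by running an ensemble under known
#' ("true") parameters and applying multiplicative noise of
#' coefficient-of-variation `noise_cv` per entry (truncated to stay
#' positive). With `noise_cv = 0` the reference equals the ensemble mean.
#' Used for self-contained parameter-recovery and baseline-direction
#' experiments, in place of biological reference means.
#'
#' @param true_params a `model_params`
#' @param cond a `sim_condition`
#' @param n_runs ensemble size
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param seed seed for the ensemble and the noise
#' @param duration,readout,grid as in [run_ensemble()]
#' @return named 6-vector with attributes `provenance` (`"synthetic"`) and
#'   `true_mean`
#' @export
synth_reference <- function(true_params, cond = condition("FM"),
                            n_runs = 100, noise_cv = 0, seed = 1,
                            duration = 180, readout = duration,
                            grid = build_grid()) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  ens <- run_ensemble(true_params, cond, n_runs = n_runs,
                      duration = duration, readout = readout,
                      seed = seed, grid = grid)
  m <- ens$mean
  set.seed(seed + 777L)
  fac <- pmax(1 + stats::rnorm(6, 0, noise_cv), 0.05)
  ref <- m * fac
  attr(ref, "provenance") <- "synthetic"
  attr(ref, "true_mean") <- m
  ref
}
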