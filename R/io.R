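#' Build a run configuration
#'
#' Assembles and validates the configuration driving the command-level
#' entry points: model variant, geometry, parameter overrides, condition,
#' ensemble size, duration, readout, seed and snapshot cadence. Unknown
#' parameter names are rejected (strict schema).
#'
#' @param model_variant `"core"` or `"integrative"`
#' @param geometry list with `cell_diameter_um`, `nucleus_diameter_um`,
#'   `patch_size_um`
#' @param params named list of `model_params` overrides
#' @param condition list with any of `medium`, `baf`, `uptake_scale`,
#'   `ap_toward_nucleus_override`, `metabolism_scale`
#' @param runs ensemble size
#' @param duration_min,readout_min run length and readout (min)
#' @param seed master seed
#' @param snapshot_every snapshot cadence in min (for [cmd_snapshot()])
#' @return a list of class `run_config`
#' @export
run_config <- function(model_variant = c("integrative", "core"),
                       geometry = list(), params = list(),
                       condition = list(), runs = 100,
                       duration_min = 180, readout_min = duration_min,
                       seed = 1, snapshot_every = 60) {
  model_variant <- match.arg(model_variant)
  geo <- utils::modifyList(
    list(cell_diameter_um = 30, nucleus_diameter_um = 10,
         patch_size_um = 0.5), geometry)
  allowed_geo <- c("cell_diameter_um", "nucleus_diameter_um",
                   "patch_size_um")
  if (length(setdiff(names(geo), allowed_geo)))
    stop("unknown geometry field(s): ",
         paste(setdiff(names(geo), allowed_geo), collapse = ", "))
  base <- if (model_variant == "core") core_params() else
    integrative_params()
  if (length(params)) {
    bad <- setdiff(names(params), names(base))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    base[names(params)] <- params
    base <- validate_params(base)
  }
  allowed_cond <- c("medium", "baf", "uptake_scale",
                    "ap_toward_nucleus_override", "metabolism_scale")
  if (length(setdiff(names(condition), allowed_cond)))
    stop("unknown condition field(s): ",
         paste(setdiff(names(condition), allowed_cond), collapse = ", "))
  cond <- do.call(autophagosim::condition, condition)
  if (duration_min < 1 || runs < 1 || snapshot_every < 1)
    stop("runs, duration_min and snapshot_every must be >= 1")
  structure(list(model_variant = model_variant, geometry = geo,
                 params = base, condition = cond, runs = runs,
                 duration_min = duration_min, readout_min = readout_min,
                 seed = seed, snapshot_every = snapshot_every),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be .yaml/.yml or .json"))
  do.call(run_config, lst)
}

.config_grid <- function(config)
  build_grid(config$geometry$cell_diameter_um,
             config$geometry$nucleus_diameter_um,
             config$geometry$patch_size_um)

# echo of a config for output metadata (params flattened to plain lists)
.config_echo <- function(config) {
  list(model_variant = config$model_variant, geometry = config$geometry,
       params = unclass(config$params),
       condition = unclass(config$condition)[
         !vapply(unclass(config$condition), is.null, logical(1))],
       runs = config$runs, duration_min = config$duration_min,
       readout_min = config$readout_min, seed = config$seed,
       snapshot_every = config$snapshot_every)
}

#' Simulate an ensemble and write time-course and summary files
#'
#' Runs the configured ensemble and writes, under `out_dir`:
#' `timecourse.csv` (per tick and vesicle kind: mean, 25% and 75% quantile
#' of count and mean size across runs, plus mean free/bound nutrients),
#' `summary.json` (readout mean/sd/q25/q75 per component, abort events,
#' per-run seeds, and a lossless echo of the configuration) and a one-line
#' per-run `run_log.txt`.
#'
#' @param config a `run_config`
#' @param out_dir output directory (created if missing)
#' @return invisibly, a list with the written paths and the
#'   `sim_ensemble`
#' @export
cmd_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- .config_grid(config)
  ens <- run_ensemble(config$params, config$condition, n_runs = config$runs,
                      duration = config$duration_min,
                      readout = config$readout_min, seed = config$seed,
                      grid = grid, keep_timecourses = TRUE)

  kinds <- c("pp", "ap", "ly", "al")
  rows <- list()
  for (t in 0:config$duration_min) {
    slice <- lapply(ens$timecourses, function(tc) tc[tc$tick == t, ])
    slice <- slice[vapply(slice, nrow, integer(1)) == 1]
    if (!length(slice)) next
    sl <- do.call(rbind, slice)
    for (k in kinds) {
      cnt <- sl[[paste0(k, "_count")]]
      sz <- sl[[paste0(k, "_size")]]
      rows[[length(rows) + 1]] <- data.frame(
        tick = t, kind = toupper(k), n_runs = nrow(sl),
        count_mean = mean(cnt),
        count_q25 = unname(stats::quantile(cnt, 0.25)),
        count_q75 = unname(stats::quantile(cnt, 0.75)),
        size_mean = mean(sz),
        size_q25 = unname(stats::quantile(sz, 0.25)),
        size_q75 = unname(stats::quantile(sz, 0.75)),
        mean_free = mean(sl$mean_free), mean_bound = mean(sl$mean_bound))
    }
  }
  tc_path <- file.path(out_dir, "timecourse.csv")
  utils::write.csv(do.call(rbind, rows), tc_path, row.names = FALSE)

  sm_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    readout_min = config$readout_min,
    mean = as.list(ens$mean), sd = as.list(ens$sd),
    q25 = as.list(ens$q25), q75 = as.list(ens$q75),
    n_aborted = ens$n_aborted, seeds = ens$seeds,
    config = .config_echo(config)
  ), sm_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  log_path <- file.path(out_dir, "run_log.txt")
  lines <- vapply(seq_len(config$runs), function(i) {
    tc <- ens$timecourses[[i]]
    ab <- attr(tc, "aborted")
    sprintf("run %d seed %d ticks %d%s", i, ens$seeds[i], nrow(tc) - 1,
            if (isTRUE(ab)) sprintf(" ABORT t=%g (%s)",
                                    attr(tc, "abort_tick"),
                                    attr(tc, "abort_reason")) else "")
  }, character(1))
  writeLines(lines, log_path)
  invisible(list(timecourse = tc_path, summary = sm_path, log = log_path,
                 ensemble = ens))
}

#' Read a six-component reference file
#'
#' CSV with columns `condition`, `count_ap`, `count_ly`, `count_al`,
#' `size_ap`, `size_ly`, `size_al` and optionally `provenance`. The
#' package ships a clearly labelled placeholder fixture
#' (`inst/extdata/reference_placeholder_synthetic.csv`) whose values are
#' synthetic stand-ins to be replaced by measured vesicle statistics.
#'
#' @param path CSV path
#' @return named list of 6-vectors, one per condition row
#' @export
read_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "count_ap", "count_ly", "count_al",
            "size_ap", "size_ly", "size_al")
  if (!all(need %in% names(df)))
    stop("reference file needs columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    unlist(df[i, need[-1]]))
  names(out) <- df$condition
  out
}

#' Fit parameters from a configuration and write a report
#'
#' Wraps [fit_ga()] and [random_baseline()]: calibrates the free
#' parameters of `space` against `reference`, compares the result with
#' `baseline_sets` random parameter sets, and writes `fit_report.json`
#' plus `fitness_trace.csv` under `out_dir`.
#'
#' @param config a `run_config` (its params are the fixed template)
#' @param space a `search_space`
#' @param reference a named 6-vector (or list of them matching `conds`)
#' @param out_dir output directory
#' @param ga a `ga_config`
#' @param baseline_sets random sets for the baseline comparison
#' @return invisibly, the list returned by [fit_ga()] plus `baseline`
#' @export
cmd_fit <- function(config, space, reference, out_dir, ga = ga_config(),
                    baseline_sets = 20) {
  if (is.null(reference)) stop("reference data required; see read_reference()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- .config_grid(config)
  fitres <- fit_ga(space, config$params, config$condition, reference,
                   ga = ga, n_runs = config$runs,
                   duration = config$duration_min,
                   readout = config$readout_min, grid = grid)
  base <- random_baseline(space, config$params, config$condition, reference,
                          n_sets = baseline_sets, n_runs = config$runs,
                          duration = config$duration_min,
                          readout = config$readout_min,
                          seed = ga$seed + 5000L, grid = grid)
  utils::write.csv(fitres$trace,
                   file.path(out_dir, "fitness_trace.csv"),
                   row.names = FALSE)
  fixed <- setdiff(names(config$params), space$names)
  jsonlite::write_json(list(
    best_fitness = fitres$best_fitness,
    best_params = as.list(fitres$best_vector),
    fixed_params = unclass(config$params)[fixed],
    baseline = list(n_sets = baseline_sets, mean = base$mean,
                    best = base$min),
    ga = unclass(ga), config = .config_echo(config)
  ), file.path(out_dir, "fit_report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(c(fitres, list(baseline = base)))
}

#' Radial occupancy over nuclear / perinuclear / peripheral bands
#'
#' Partitions the cell into radial bands: `N` inside the nuclear radius,
#' `M` (perinuclear) between the nucleus and the mid-radius equidistant
#' between nucleus and periphery (10 um by default geometry), `P` outside
#' the mid-radius. Returns the fraction of the selected agents in each
#' band, together with the cytosol-area fractions of the M and P bands
#' (the uniform-placement null).
#'
#' @param pool an `agent_pool`
#' @param grid a `grid_spec`
#' @param kinds integer or character kinds to include (default all)
#' @return named list: `fractions` (N/M/P), `counts`, `null` (area
#'   fractions of M and P within the cytosol annulus)
#' @export
nmp_occupancy <- function(pool, grid, kinds = 1:4) {
  if (is.character(kinds)) kinds <- agent_kinds[kinds]
  sel <- pool$kind %in% kinds
  r <- sqrt(pool$x[sel]^2 + pool$y[sel]^2)
  mid <- (grid$r_nuc + grid$r_cell) / 2
  # the nuclear band is the open disk: vesicles clamped on the nuclear
  # envelope itself are perinuclear
  counts <- c(N = sum(r < grid$r_nuc),
              M = sum(r >= grid$r_nuc & r <= mid),
              P = sum(r > mid))
  tot <- sum(counts)
  a_m <- mid^2 - grid$r_nuc^2
  a_p <- grid$r_cell^2 - mid^2
  list(fractions = if (tot > 0) counts / tot else counts * NA_real_,
       counts = counts,
       null = c(M = a_m / (a_m + a_p), P = a_p / (a_m + a_p)))
}

#' Run one simulation and write periodic agent/nutrient snapshots
#'
#' Advances a single run, capturing at every `snapshot_every` minutes the
#' full agent table (tick, id, kind, position, size, cargo), the radial
#' N/M/P occupancy, and (integrative variant) the per-patch nutrient
#' field. Writes `agents.csv`, `occupancy.csv` and `field.csv` under
#' `out_dir`.
#'
#' @param config a `run_config`
#' @param out_dir output directory
#' @return invisibly, a list with the snapshot data frames and paths
#' @export
cmd_snapshot <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- .config_grid(config)
  state <- initialize_state(config$params, config$condition, grid,
                            seed = config$seed)
  cadence <- config$snapshot_every
  agents <- list(); occ <- list(); fld <- list()
  take <- function(s) {
    df <- as.data.frame(s$pool)
    df <- cbind(tick = s$tick, df[c("id", "kind", "x", "y", "size", "cargo")])
    names(df)[4:5] <- c("x_um", "y_um")
    names(df)[6] <- "size_um2"
    agents[[length(agents) + 1]] <<- df
    oc <- nmp_occupancy(s$pool, grid)
    occ[[length(occ) + 1]] <<- data.frame(
      tick = s$tick, t(oc$fractions), null_M = oc$null[["M"]])
    if (!is.null(s$field)) {
      w <- which(grid$cytosol, arr.ind = TRUE)
      fld[[length(fld) + 1]] <<- data.frame(
        tick = s$tick, patch_ix = w[, 1] - 1L, patch_iy = w[, 2] - 1L,
        free = s$field$free[grid$cytosol],
        bound = s$field$bound[grid$cytosol])
    }
  }
  take(state)
  for (t in seq_len(config$duration_min)) {
    state <- tick(state, config$params, config$condition, grid)
    if (state$tick %% cadence == 0 || state$aborted) take(state)
    if (state$aborted) break
  }
  paths <- list(agents = file.path(out_dir, "agents.csv"),
                occupancy = file.path(out_dir, "occupancy.csv"),
                field = file.path(out_dir, "field.csv"))
  utils::write.csv(do.call(rbind, agents), paths$agents, row.names = FALSE)
  utils::write.csv(do.call(rbind, occ), paths$occupancy, row.names = FALSE)
  if (length(fld))
    utils::write.csv(do.call(rbind, fld), paths$field, row.names = FALSE)
  invisible(list(agents = do.call(rbind, agents),
                 occupancy = do.call(rbind, occ),
                 field = if (length(fld)) do.call(rbind, fld) else NULL,
                 paths = paths))
}
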