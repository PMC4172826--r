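#' Model parameter sets
#'
#' `core_params()` returns the fitted parameter set of the core vesicle-only
#' model; `integrative_params()` the fitted set of the nutrient-integrative
#' model. All values are per-minute rates, um^2 sizes/growth rates, minutes,
#' or probabilities, named in snake_case. Any entry can be overridden through
#' `...`; unknown names are rejected.
#'
#' The two variants differ in how autolysosomes die: the core model samples a
#' lifetime at formation (`al_lifetime_mean`, exponential by default), the
#' integrative model applies a per-tick death probability
#' (`al_degradation_rate`, scaled by the nutrient deficit and by Bafilomycin
#' A1). Under BAF the degradation is attenuated by
#' `baf_degradation_factor` (default 0.05, i.e. a factor-20 reduction); in
#' lifetime mode the same factor multiplies the mean lifetime's inverse.
#'
#' @param ... named overrides of individual parameters
#' @return a named list of class `model_params` with attribute
#'   `variant` `"core"` or `"integrative"`
#' @export
core_params <- function(...) {
  p <- list(
    # initial census and sizes
    initial_pp = 3, initial_ap = 31, initial_ly = 19, initial_al = 28,
    pp_initial_size = 0.06, ly_initial_size = 0.095, al_initial_size = 0.225,
    # creation / maturation / lifetimes (min^-1, min)
    pp_creation_rate = 0.42, ly_creation_rate = 1.26,
    pp_maturation_mean = 7.5, ly_lifetime_mean = 18, al_lifetime_mean = 95,
    al_degradation_rate = NA_real_,
    # growth rates (um^2 min^-1)
    pp_growth = 6e-4, ap_growth = 8e-5, ly_growth = 0.002, al_growth = 0.0012,
    # movement
    movement_speed = 2, ap_toward_nucleus = 0.85, ly_toward_nucleus = 0.55,
    # fusion / reformation
    fusion_non_al_al = 0.45, fusion_al_al = 0.15, ap_ly_fusion = 1,
    reformation_chance = 0.5, contact_radius = 0.5,
    # condition handling and guards
    baf_degradation_factor = 0.05, agent_cap = 500,
    lifetime_distribution = "exponential",
    # nutrient coupling (unused by the core variant; kept for a uniform shape)
    pp_nutrient_linear = 0, pp_nutrient_exp = 1,
    ly_nutrient_linear = 0, ly_nutrient_exp = 1,
    al_nutrient_linear = 0, al_nutrient_exp = 1,
    ly_positioning_slope = 0,
    # nutrient field (inactive in the core variant)
    free_init = 20, bound_init = 20,
    free_diffusion = 0.7, bound_diffusion = 0.5,
    border_influx = 1.1, free_decay = 0.05, conversion_rate = 0.045,
    ly_recycling = 1.5, ap_uptake = 2.25, al_release = 2.25,
    decay_pool = "free"
  )
  .apply_overrides(p, list(...), "core")
}

#' @rdname core_params
#' @export
integrative_params <- function(...) {
  p <- core_params()
  attr(p, "variant") <- NULL
  upd <- list(
    pp_initial_size = 0.07, pp_creation_rate = 0.44,
    pp_nutrient_linear = 0.206, pp_nutrient_exp = 1.179,
    pp_growth = 5e-4,
    ly_initial_size = 0.1, ly_creation_rate = 1.23,
    ly_nutrient_linear = 0.112, ly_nutrient_exp = 1.124,
    ly_growth = 0.0021,
    al_degradation_rate = 0.15, al_lifetime_mean = NA_real_,
    al_nutrient_linear = 0.0069, al_nutrient_exp = 3.14,
    al_growth = 6.5e-4,
    ly_positioning_slope = 0.005,
    fusion_al_al = 0.30
  )
  p[names(upd)] <- upd
  .apply_overrides(p, list(...), "integrative")
}

.apply_overrides <- function(p, dots, variant) {
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(structure(p, class = "model_params", variant = variant))
}

#' Validate a parameter set
#'
#' Checks probability ranges, non-negativity of rates/sizes/means and that
#' the agent cap can hold the initial census. Returns its argument invisibly
#' on success.
#' @param p a `model_params` object
#' @export
validate_params <- function(p) {
  probs <- c("ap_toward_nucleus", "ly_toward_nucleus", "fusion_non_al_al",
             "fusion_al_al", "ap_ly_fusion", "reformation_chance",
             "free_diffusion", "bound_diffusion")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("parameter ", nm, " must be a probability in [0, 1]")
  nonneg <- c("initial_pp", "initial_ap", "initial_ly", "initial_al",
              "pp_initial_size", "ly_initial_size", "al_initial_size",
              "pp_creation_rate", "ly_creation_rate", "pp_maturation_mean",
              "ly_lifetime_mean", "pp_growth", "ap_growth", "ly_growth",
              "al_growth", "movement_speed", "contact_radius",
              "border_influx", "free_decay", "conversion_rate",
              "ly_recycling", "ap_uptake", "al_release",
              "free_init", "bound_init")
  for (nm in nonneg)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("parameter ", nm, " must be finite and >= 0")
  total0 <- p$initial_pp + p$initial_ap + p$initial_ly + p$initial_al
  if (p$agent_cap < total0)
    stop("agent_cap (", p$agent_cap, ") below initial census (", total0, ")")
  if (!p$lifetime_distribution %in% c("exponential", "fixed"))
    stop("lifetime_distribution must be 'exponential' or 'fixed'")
  if (!p$decay_pool %in% c("free", "bound"))
    stop("decay_pool must be 'free' or 'bound'")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %s variant, %d parameters\n",
              attr(x, "variant"), length(x)))
  invisible(x)
}

#' Experimental condition descriptor
#'
#' @param medium `"FM"` (full medium) or `"ND"` (nutrient deprivation; sets
#'   the default `uptake_scale` to 0, i.e. no boundary influx of free
#'   nutrients)
#' @param baf logical; Bafilomycin A1 present (attenuates autolysosomal
#'   degradation by `baf_degradation_factor`)
#' @param uptake_scale multiplier on the boundary nutrient influx; defaults
#'   to 1 under FM and 0 under ND
#' @param ap_toward_nucleus_override optional probability replacing the
#'   autophagosome inward-transport probability (long-term perturbations)
#' @param metabolism_scale multiplier on the free-to-bound conversion rate
#' @return a list of class `sim_condition`
#' @export
condition <- function(medium = c("FM", "ND"), baf = FALSE,
                      uptake_scale = NULL,
                      ap_toward_nucleus_override = NULL,
                      metabolism_scale = 1) {
  medium <- match.arg(medium)
  if (is.null(uptake_scale)) uptake_scale <- if (medium == "ND") 0 else 1
  if (uptake_scale < 0) stop("uptake_scale must be >= 0")
  if (!is.null(ap_toward_nucleus_override) &&
      (ap_toward_nucleus_override < 0 || ap_toward_nucleus_override > 1))
    stop("ap_toward_nucleus_override must be a probability")
  structure(list(
    medium = medium, baf = isTRUE(baf), uptake_scale = uptake_scale,
    ap_toward_nucleus_override = ap_toward_nucleus_override,
    metabolism_scale = metabolism_scale
  ), class = "sim_condition")
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf("<condition> %s%s, uptake x%g, metabolism x%g%s\n",
              x$medium, if (x$baf) " + BAF" else "", x$uptake_scale,
              x$metabolism_scale,
              if (!is.null(x$ap_toward_nucleus_override))
                sprintf(", AP inward %g", x$ap_toward_nucleus_override)
              else ""))
  invisible(x)
}
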