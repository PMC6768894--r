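#' Exposure scenarios
#'
#' A scenario is an ordered, contiguous sequence of exposure phases. Each
#' phase carries a kind (`"bath"`, `"rest"` or `"air_inhalation"`), a
#' duration in minutes, the radon concentration in water (`c_water`, bath
#' phases, Bq m^-3), the room-air concentration in contact with dry skin
#' (`c_air`, Bq m^-3), the concentration of the inhaled air (`c_inhale`,
#' Bq m^-3; in the bathtub protocol the volunteers breathe nearly radon-free
#' outside air through a mask, so it differs from the room air), optional
#' modulation overrides, and a pre-heating flag.
#'
#' @param phases list of phase lists (see [rn_phase()]).
#' @param label scenario name.
#' @return an object of class `rn_scenario`.
#' @export
rn_scenario <- function(phases, label = "scenario") {
  if (length(phases) == 0L) stop("a scenario needs at least one phase")
  for (p in phases) {
    if (!p$kind %in% c("bath", "rest", "air_inhalation"))
      stop("unknown phase kind: ", p$kind)
    if (p$duration_min < 0) stop("phase durations must be non-negative")
    if (p$kind == "bath" && (p$c_water %||% 0) < 0)
      stop("bath phases need c_water >= 0")
    if ((p$c_air %||% 0) < 0 || (p$c_inhale %||% 0) < 0)
      stop("air concentrations must be >= 0")
  }
  structure(list(phases = phases, label = label), class = "rn_scenario")
}

#' @rdname rn_scenario
#' @param kind phase kind.
#' @param duration_min phase duration (minutes).
#' @param c_water radon concentration in the bath water (Bq m^-3).
#' @param c_air radon concentration of the room air at the skin (Bq m^-3).
#' @param c_inhale radon concentration of the inhaled air (Bq m^-3);
#'   defaults to `c_air`.
#' @param modulation named list overriding entries of the parameter set's
#'   modulation settings for this phase (e.g. `list(apply_swelling = TRUE)`).
#' @param preheated logical; the temperature ramp is complete at phase start.
#' @export
rn_phase <- function(kind, duration_min, c_water = 0, c_air = 0,
                     c_inhale = NULL, modulation = NULL, preheated = FALSE) {
  list(kind = kind, duration_min = duration_min, c_water = c_water,
       c_air = c_air, c_inhale = c_inhale %||% c_air,
       modulation = modulation, preheated = preheated)
}

#' Standard bathtub protocol
#'
#' The measurement protocol of the study: a bath in radon-rich thermal water
#' followed by a resting phase out of the water. The subject breathes
#' near-radon-free outside air through a mask during both phases, while the
#' room air (about 100 Bq m^-3) contacts the dry, non-immersed skin.
#'
#' @param c_water radon concentration of the thermal water (Bq m^-3;
#'   default 0.9 MBq m^-3, the typical treatment level).
#' @param bath_min,rest_min phase durations (minutes); 30-minute baths probe
#'   the saturation of the exhalation curve.
#' @param c_air room-air concentration at the skin (Bq m^-3).
#' @param c_mask concentration of the inhaled mask air (Bq m^-3).
#' @param apply_swelling logical; enable the stratum-corneum swelling decline
#'   of the permeability (saturation-type subjects).
#' @param preheated logical; subject pre-heated in radon-free water, so the
#'   temperature ramp starts saturated.
#' @return an [rn_scenario()] with a bath and a rest phase.
#' @examples
#' sc <- bath_scenario(c_water = 0.9e6)
#' sum(vapply(sc$phases, function(p) p$duration_min, 1))  # 40 min
#' @export
bath_scenario <- function(c_water = 0.9e6, bath_min = 20, rest_min = 20,
                          c_air = 100, c_mask = 10, apply_swelling = FALSE,
                          preheated = FALSE) {
  stopifnot(c_water >= 0, bath_min > 0, rest_min > 0)
  rn_scenario(list(
    rn_phase("bath", bath_min, c_water = c_water, c_air = c_air,
             c_inhale = c_mask,
             modulation = list(apply_swelling = apply_swelling),
             preheated = preheated),
    rn_phase("rest", rest_min, c_air = c_air, c_inhale = c_mask)),
    label = sprintf("bath %g min + rest %g min%s%s", bath_min, rest_min,
                    if (apply_swelling) " (swelling)" else "",
                    if (preheated) " (preheated)" else ""))
}

#' Continuous-inhalation validation protocol
#'
#' Exposure to a constant elevated radon concentration in air of
#' 25.9 Bq l^-1 (25 900 Bq m^-3) for 8.5 h followed by a 120 h clean-air
#' washout, used to verify that the skin-extended model reproduces the
#' whole-body retention behaviour of the base circulation model. Skin
#' modulation is off (no immersion); the skin exchanges with air at the
#' dry-skin permeability.
#'
#' @param c_air exposure concentration (Bq m^-3).
#' @param exposure_h,washout_h phase durations (hours).
#' @return an [rn_scenario()].
#' @export
inhalation_validation_scenario <- function(c_air = 25900, exposure_h = 8.5,
                                           washout_h = 120) {
  rn_scenario(list(
    rn_phase("air_inhalation", exposure_h * 60, c_air = c_air),
    rn_phase("air_inhalation", washout_h * 60, c_air = 0)),
    label = sprintf("inhalation %g h at %g Bq m^-3 + washout %g h",
                    exposure_h, c_air, washout_h))
}

#' Environmental background inhalation
#'
#' Continuous inhalation of air at the indoor background level (default
#' 100 Bq m^-3), used to overlay the unavoidable environmental contribution
#' on the post-bath organ concentration curves.
#'
#' @param c_air air concentration (Bq m^-3).
#' @param duration_h duration (hours).
#' @return an [rn_scenario()].
#' @export
environmental_scenario <- function(c_air = 100, duration_h = 24) {
  rn_scenario(list(rn_phase("air_inhalation", duration_h * 60, c_air = c_air)),
              label = sprintf("environmental %g Bq m^-3 for %g h",
                              c_air, duration_h))
}

#' Total scenario duration in minutes
#' @param scenario an [rn_scenario()].
#' @export
scenario_duration_min <- function(scenario) {
  sum(vapply(scenario$phases, function(p) p$duration_min, numeric(1)))
}

#' @export
print.rn_scenario <- function(x, ...) {
  cat(sprintf("Exposure scenario '%s' (%g min):\n", x$label,
              scenario_duration_min(x)))
  for (p in x$phases)
    cat(sprintf("  %-15s %7g min  C_W %g, C_air %g, C_inhale %g Bq m^-3%s%s\n",
                p$kind, p$duration_min, p$c_water %||% 0, p$c_air %||% 0,
                p$c_inhale %||% 0,
                if (isTRUE(p$preheated)) ", preheated" else "",
                if (isTRUE((p$modulation %||% list())$apply_swelling))
                  ", swelling" else ""))
  invisible(x)
}

#' Read and write scenarios as YAML
#'
#' @param scenario an [rn_scenario()].
#' @param path file path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns an [rn_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  writeLines(yaml::as.yaml(unclass(scenario), precision = 17L), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::yaml.load_file(path)
  rn_scenario(x$phases, label = x$label %||% "scenario")
}
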