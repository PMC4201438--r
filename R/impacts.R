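#' Specify a disturbance impact
#'
#' An impact is abstracted by two expert-elicited scores on `[0, 1]`: its
#' intensity `I` and the fraction `S` of the forest it touches (spatial
#' scale). At scenario start all trees in a strip covering fraction `S` of
#' the sample hectare are removed (single killing event), and during recovery
#' both recruitment and diameter growth inside that strip are reduced.
#'
#' Two reduction formulas are available. `"literal"` follows the published
#' scenario table: factor `1 - I * (1 - S)`. Because that weakens the
#' reduction as `S` grows, the alternative `"zone_intensity"` mode uses
#' `1 - I` inside the zone, independent of `S`.
#'
#' @param name Impact label, e.g. `"development"`.
#' @param intensity Impact intensity `I` in `[0, 1]`.
#' @param spatial_scale Affected-area fraction `S` in `[0, 1]`.
#' @param formula_mode `"literal"` or `"zone_intensity"` (see Details).
#' @return An object of class `impact_spec`.
#' @examples
#' impact_spec("development", intensity = 0.8, spatial_scale = 0.8)
#' @export
impact_spec <- function(name, intensity, spatial_scale,
                        formula_mode = c("literal", "zone_intensity")) {
  formula_mode <- match.arg(formula_mode)
  if (!is.numeric(intensity) || intensity < 0 || intensity > 1 ||
      !is.numeric(spatial_scale) || spatial_scale < 0 || spatial_scale > 1) {
    stop("intensity and spatial_scale must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      name = as.character(name), intensity = intensity,
      spatial_scale = spatial_scale, formula_mode = formula_mode
    ),
    class = "impact_spec"
  )
}

#' @export
print.impact_spec <- function(x, ...) {
  cat(sprintf(
    "<impact_spec> %s: intensity %.2f, spatial scale %.2f (%s mode)\n",
    x$name, x$intensity, x$spatial_scale, x$formula_mode
  ))
  invisible(x)
}

#' Read a list of impacts from a JSON file
#'
#' Expects a top-level `impacts` array of objects with fields `name`,
#' `intensity`, `spatial_scale` and optionally `formula_mode`.
#'
#' @param path Path to a JSON file.
#' @return A list of [impact_spec()] objects.
#' @export
read_impacts <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$impacts)) {
    stop("configuration file has no `impacts` array: ", path, call. = FALSE)
  }
  purrr::map(cfg$impacts, ~ do.call(impact_spec, .x))
}

#' The strip cleared by an impact of spatial scale S
#'
#' The impacted zone is a rectangular strip covering fraction `S` of the
#' sample square, anchored at its left edge and extended through the edge
#' band over the full y-range of the domain.
#'
#' @param S Spatial scale in `[0, 1]`.
#' @param stand A [new_stand()] object (for the geometry).
#' @return List with `x_min`, `x_max` (m); an empty zone when `S = 0`.
#' @export
impacted_zone <- function(S, stand = new_stand()) {
  stopifnot(S >= 0, S <= 1)
  list(
    x_min = stand$sample_origin,
    x_max = stand$sample_origin + S * stand$sample_side
  )
}

#' Regrowth reduction factors of an impact
#'
#' In `"literal"` mode both the recruit and the growth factor inside the zone
#' are `1 - I * (1 - S)`; in `"zone_intensity"` mode they are `1 - I`.
#' Outside the zone both factors are always 1. Factors are clipped to
#' `[0, 1]`.
#'
#' @param spec An [impact_spec()].
#' @return A list with `recruit_factor` and `growth_factor`.
#' @examples
#' zone_modifiers(impact_spec("x", 0.8, 0.8)) # 1 - 0.8*0.2 = 0.84
#' @export
zone_modifiers <- function(spec) {
  f <- switch(spec$formula_mode,
    literal = 1 - spec$intensity * (1 - spec$spatial_scale),
    zone_intensity = 1 - spec$intensity
  )
  f <- min(1, max(0, f))
  list(recruit_factor = f, growth_factor = f)
}

#' Impose an impact on an equilibrium stand
#'
#' Removes every tree inside [impacted_zone()] in a single killing event
#' (`mode = "clear"`, the default) or thins the zone by the factor
#' `1 - I * (1 - S)` (`mode = "thin"`, the scenario table's density row), and
#' installs the zone's regrowth factors on the stand. Trees outside the zone
#' are untouched.
#'
#' @param stand A [new_stand()] object, typically at spinup equilibrium.
#' @param spec An [impact_spec()].
#' @param mode `"clear"` or `"thin"`.
#' @return The disturbed stand (year unchanged).
#' @export
apply_impact <- function(stand, spec, mode = c("clear", "thin")) {
  mode <- match.arg(mode)
  if (!inherits(spec, "impact_spec")) {
    stop("spec must be an impact_spec", call. = FALSE)
  }
  z <- impacted_zone(spec$spatial_scale, stand)
  in_zone <- stand$trees$x >= z$x_min & stand$trees$x < z$x_max
  kill <- switch(mode,
    clear = in_zone,
    thin = in_zone &
      runif(nrow(stand$trees)) >= (1 - spec$intensity * (1 - spec$spatial_scale))
  )
  stand$trees <- stand$trees[!kill, ]
  mods <- zone_modifiers(spec)
  stand$zone <- c(z, mods)
  stand
}

#' Time to regrow into the healthy-biomass band
#'
#' Runs [step_year()] until the sample-hectare biomass re-enters the healthy
#' band, declared at its lower edge. Returns the elapsed years; if the band
#' is not reached within `max_years` the result is censored at that horizon
#' (never an error).
#'
#' @param stand A disturbed stand (see [apply_impact()]).
#' @param params A [species_params()] object.
#' @param band Healthy biomass band (t/ha); recovery at `band[1]`.
#' @param max_years Censoring horizon (years).
#' @param base_rate Undisturbed recruitment rate (per ha per yr).
#' @return One-row tibble: `years`, `censored`, `biomass_t_ha` at stop.
#' @export
recovery_time <- function(stand, params = species_params(),
                          band = c(300, 400), max_years = 200,
                          base_rate = 390) {
  stopifnot(band[1] < band[2])
  bm <- stand_summary(stand, params)$biomass_t_ha
  years <- 0
  while (bm < band[1] && years < max_years) {
    stand <- step_year(stand, params, base_rate)
    years <- years + 1
    bm <- stand_summary(stand, params)$biomass_t_ha
  }
  tibble::tibble(
    years = years, censored = bm < band[1], biomass_t_ha = bm
  )
}
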