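#' Species parameters for the stand simulator
#'
#' Bundles the biological constants of the (single) simulated species,
#' *Rhizophora apiculata*. Defaults were fixed by [calibrate()] against the
#' Matang reference stand anchors (1344 trees/ha, 31.89 m2/ha basal area,
#' ~375 t/ha equilibrium biomass); every constant is overridable.
#'
#' @param d_max Maximum stem diameter at breast height (cm).
#' @param h_max Maximum tree height (cm); 5000 cm = 50 m.
#' @param g_growth Intrinsic JABOWA growth constant (cm scale).
#' @param fon_a,fon_b Field-of-neighborhood radius scaling: the FON radius is
#'   `fon_a * r_stem^fon_b` metres with `r_stem = dbh/200` the stem radius (m).
#' @param fon_min FON intensity at the FON boundary, in (0, 1).
#' @param comp_slope Slope `c` of the competition growth multiplier
#'   `max(0, 1 - c * F)` applied to diameter increments.
#' @param allom_s,allom_t Above-ground biomass allometry `B = allom_s *
#'   dbh^allom_t` (kg, dbh in cm).
#' @param suppression_threshold A tree whose 5-year mean relative diameter
#'   increment falls below this value (per year) counts as suppressed.
#' @param p_die_suppressed Annual death probability while suppressed.
#' @param recruit_dbh Diameter (cm) assigned to a newly established sapling.
#' @param max_age Optional maximum age (years); trees older than this die.
#'   `Inf` disables the cap.
#' @param resolution Quadrature grid spacing (m) for FON competition integrals.
#'
#' @return An object of class `species_params` (a validated named list).
#' @examples
#' p <- species_params()
#' p$d_max
#' @export
species_params <- function(d_max = 70,
                           h_max = 5000,
                           g_growth = 275,
                           fon_a = 10,
                           fon_b = 0.5,
                           fon_min = 0.1,
                           comp_slope = 1,
                           allom_s = 0.222,
                           allom_t = 2.42,
                           suppression_threshold = 0.003,
                           p_die_suppressed = 0.3,
                           recruit_dbh = 1.0,
                           max_age = Inf,
                           resolution = 0.25) {
  p <- list(
    d_max = d_max, h_max = h_max, g_growth = g_growth,
    fon_a = fon_a, fon_b = fon_b, fon_min = fon_min,
    comp_slope = comp_slope, allom_s = allom_s, allom_t = allom_t,
    suppression_threshold = suppression_threshold,
    p_die_suppressed = p_die_suppressed,
    recruit_dbh = recruit_dbh, max_age = max_age, resolution = resolution
  )
  validate_species_params(p)
  structure(p, class = "species_params")
}

validate_species_params <- function(p) {
  stopifnot(
    p$d_max > 0, p$h_max > 137,
    p$g_growth > 0,
    p$fon_a > 0, p$fon_b >= 0,
    p$fon_min > 0, p$fon_min < 1,
    p$comp_slope > 0,
    p$allom_s > 0, p$allom_t > 0,
    p$suppression_threshold >= 0,
    p$p_die_suppressed >= 0, p$p_die_suppressed <= 1,
    p$recruit_dbh > 0, p$recruit_dbh <= p$d_max,
    p$max_age > 0,
    p$resolution > 0
  )
  invisible(p)
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read species parameters from a JSON configuration file
#'
#' The file must contain a top-level `species` object whose fields match the
#' arguments of [species_params()]; missing fields keep their defaults.
#'
#' @param path Path to a JSON file.
#' @return A `species_params` object.
#' @export
read_species_params <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$species)) {
    stop("configuration file has no `species` block: ", path, call. = FALSE)
  }
  do.call(species_params, as.list(cfg$species))
}
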