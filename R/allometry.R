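#' Tree height from stem diameter
#'
#' JABOWA-family parabolic allometry `H = 137 + b2*D - b3*D^2` with `b2`,
#' `b3` chosen so that `H(0) = 137` cm (breast height) and `H(d_max) = h_max`
#' with zero slope, i.e. `b2 = 2*(h_max - 137)/d_max` and
#' `b3 = (h_max - 137)/d_max^2`.
#'
#' @param dbh Diameter(s) at breast height (cm), in `[0, d_max]`.
#' @param params A [species_params()] object.
#' @return Height (cm).
#' @export
height_from_dbh <- function(dbh, params = species_params()) {
  if (any(dbh < 0) || any(dbh > params$d_max)) {
    stop("dbh must lie in [0, d_max]", call. = FALSE)
  }
  b <- height_coefs(params)
  137 + b$b2 * dbh - b$b3 * dbh^2
}

height_coefs <- function(params) {
  list(
    b2 = 2 * (params$h_max - 137) / params$d_max,
    b3 = (params$h_max - 137) / params$d_max^2
  )
}

#' Above-ground tree biomass
#'
#' Power-law allometry `B = allom_s * dbh^allom_t` (kg). The default
#' coefficients put a 17.4 cm stem at ~223 kg, so the Matang reference stand
#' (1344 trees/ha at 31.89 m2/ha basal area) carries ~300 t/ha.
#'
#' @inheritParams height_from_dbh
#' @return Biomass (kg).
#' @export
tree_biomass <- function(dbh, params = species_params()) {
  if (any(dbh < 0)) stop("dbh must be nonnegative", call. = FALSE)
  params$allom_s * dbh^params$allom_t
}

#' Annual diameter increment
#'
#' JABOWA diameter growth reduced multiplicatively by neighborhood
#' competition and by the impact-zone growth factor:
#' \deqn{\Delta D = \frac{g D (1 - D H / (d_{max} h_{max}))}{274 + 3 b_2 D -
#'   4 b_3 D^2} \cdot \max(0, 1 - c F) \cdot z}
#' with `H = height_from_dbh(D)`, competition index `F`, competition slope
#' `c = comp_slope` and zone growth factor `z`. The increment is nonnegative,
#' vanishes at `D = d_max`, and is capped so `D` never exceeds `d_max`.
#'
#' @param dbh Diameter(s) at breast height (cm).
#' @param F Competition index (same length as `dbh` or scalar).
#' @param zone_growth_factor Growth factor(s) in `[0, 1]` from the impact zone.
#' @param params A [species_params()] object.
#' @return Diameter increment (cm/yr).
#' @examples
#' annual_growth(10, F = 0, params = species_params())
#' @export
annual_growth <- function(dbh, F = 0, zone_growth_factor = 1,
                          params = species_params()) {
  stopifnot(all(F >= 0), all(zone_growth_factor >= 0),
            all(zone_growth_factor <= 1))
  b <- height_coefs(params)
  H <- height_from_dbh(dbh, params)
  raw <- params$g_growth * dbh *
    (1 - dbh * H / (params$d_max * params$h_max)) /
    (274 + 3 * b$b2 * dbh - 4 * b$b3 * dbh^2)
  dd <- pmax(0, raw) * pmax(0, 1 - params$comp_slope * F) * zone_growth_factor
  pmin(dd, params$d_max - dbh)
}
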