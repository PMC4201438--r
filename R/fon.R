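#' Field-of-neighborhood radius
#'
#' The FON is the circular zone around a stem within which a tree exerts and
#' experiences competition. Its radius scales with stem radius as
#' `fon_a * r_stem^fon_b` (m) with `r_stem = dbh/200`, and is never smaller
#' than the stem radius itself.
#'
#' @param dbh Stem diameter(s) at breast height (cm); vectorized.
#' @param params A [species_params()] object.
#' @return FON radius (m), same length as `dbh`.
#' @examples
#' fon_radius(18, species_params(fon_a = 10, fon_b = 0.5)) # 3 m
#' @export
fon_radius <- function(dbh, params = species_params()) {
  if (any(dbh < 0)) stop("dbh must be nonnegative", call. = FALSE)
  cpp_fon_radius(as.numeric(dbh), params$fon_a, params$fon_b)
}

#' FON intensity of one tree at given points
#'
#' Intensity is 1 on the stem disc, decays exponentially from 1 to `fon_min`
#' between the stem radius and the FON radius, and is 0 beyond the FON.
#'
#' @param tree A list or one-row data frame with `x`, `y`, `dbh`.
#' @param px,py Point coordinates (m); vectorized.
#' @inheritParams fon_radius
#' @return Intensities in `[0, 1]`, one per point.
#' @export
fon_intensity <- function(tree, px, py, params = species_params()) {
  cpp_fon_field(
    as.numeric(px), as.numeric(py),
    as.numeric(tree$x), as.numeric(tree$y), as.numeric(tree$dbh),
    params$fon_a, params$fon_b, params$fon_min
  )
}

#' Summed FON field of a stand at arbitrary points
#'
#' The establishment field: the sum over all trees (optionally excluding one)
#' of their FON intensities at each point. Values above 1 indicate a closed
#' canopy where no sapling can establish.
#'
#' @param stand A [new_stand()] object.
#' @param px,py Point coordinates (m); vectorized.
#' @param exclude Index (row) of one tree to leave out, or `NULL`.
#' @inheritParams fon_radius
#' @return Numeric vector of summed intensities, one per point.
#' @export
fon_field <- function(stand, px, py, params = species_params(),
                      exclude = NULL) {
  cpp_fon_field(
    as.numeric(px), as.numeric(py),
    stand$trees$x, stand$trees$y, stand$trees$dbh,
    params$fon_a, params$fon_b, params$fon_min,
    exclude = if (is.null(exclude)) 0L else as.integer(exclude)
  )
}

#' Neighborhood competition index of every tree
#'
#' For each tree the index F is the mean, over its own FON disc, of the
#' summed FON intensities of all its neighbours: an area-normalized overlap
#' integral evaluated on a square quadrature grid (spacing at most
#' `resolution` m) clipped to the disc. F is 0 for an isolated tree and grows
#' with crowding; it feeds the growth multiplier `max(0, 1 - comp_slope * F)`.
#'
#' @param stand A [new_stand()] object.
#' @inheritParams fon_radius
#' @param resolution Quadrature grid spacing (m); defaults to the value in
#'   `params`.
#' @param cap Optional ceiling: quadrature of a tree stops once its index is
#'   provably at least `cap`, which is then returned for it. The annual
#'   update uses `cap = 1/comp_slope`, beyond which growth is zero anyway.
#' @return Numeric vector of competition indices aligned with `stand$trees`.
#' @examples
#' st <- new_stand(data.frame(x = c(60, 61), y = c(60, 60), dbh = c(20, 20)))
#' competition_index(st)
#' @export
competition_index <- function(stand, params = species_params(),
                              resolution = params$resolution, cap = Inf) {
  cpp_competition_indices(
    stand$trees$x, stand$trees$y, stand$trees$dbh,
    params$fon_a, params$fon_b, params$fon_min, resolution, cap
  )
}
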