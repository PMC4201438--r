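#' Create a stand of trees on the simulation domain
#'
#' A stand is the simulator's state: a tibble of trees on a square domain
#' whose inner square is the sampling area. The default geometry is a
#' 120 x 120 m domain whose central 100 x 100 m hectare is sampled; the 10 m
#' band around it buffers edge effects and is excluded from all summaries.
#'
#' Each tree carries its position (m), diameter at breast height (cm), age
#' (years) and a 5-slot memory `m1..m5` of its most recent annual relative
#' diameter increments (`m1` newest; `NA` = not yet recorded).
#'
#' @param trees A data frame with at least columns `x`, `y`, `dbh`; `age` and
#'   the memory slots are added if missing. `NULL` gives an empty stand.
#' @param domain_side Side of the square domain (m).
#' @param sample_origin Offset of the sampling square from the domain corner (m).
#' @param sample_side Side of the sampling square (m).
#' @param year Simulation year attached to the state.
#' @param zone Impact-zone descriptor as returned by [apply_impact()]
#'   (a list with `x_min`, `x_max`, `recruit_factor`, `growth_factor`), or
#'   `NULL` for an undisturbed stand.
#'
#' @return An object of class `stand`.
#' @examples
#' st <- new_stand(data.frame(x = 60, y = 60, dbh = 20))
#' st
#' @export
new_stand <- function(trees = NULL, domain_side = 120, sample_origin = 10,
                      sample_side = 100, year = 0, zone = NULL) {
  if (is.null(trees)) {
    trees <- tibble::tibble(x = numeric(), y = numeric(), dbh = numeric())
  }
  trees <- tibble::as_tibble(trees)
  stopifnot(all(c("x", "y", "dbh") %in% names(trees)))
  if (!"age" %in% names(trees)) trees$age <- 0
  for (m in paste0("m", 1:5)) if (!m %in% names(trees)) trees[[m]] <- NA_real_
  trees <- trees[, c("x", "y", "dbh", "age", paste0("m", 1:5))]
  if (nrow(trees) > 0) {
    stopifnot(
      all(trees$dbh > 0),
      all(trees$x >= 0 & trees$x <= domain_side),
      all(trees$y >= 0 & trees$y <= domain_side)
    )
  }
  stopifnot(
    sample_origin >= 0, sample_side > 0,
    sample_origin + sample_side <= domain_side
  )
  structure(
    list(
      trees = trees, domain_side = domain_side,
      sample_origin = sample_origin, sample_side = sample_side,
      year = year, zone = zone
    ),
    class = "stand"
  )
}

#' @export
print.stand <- function(x, ...) {
  cat(sprintf(
    "<stand> year %d: %d trees on a %g x %g m domain (%g x %g m sample square)\n",
    x$year, nrow(x$trees), x$domain_side, x$domain_side,
    x$sample_side, x$sample_side
  ))
  if (!is.null(x$zone)) {
    cat(sprintf(
      "  impact zone x in [%g, %g] m: recruit factor %.3g, growth factor %.3g\n",
      x$zone$x_min, x$zone$x_max, x$zone$recruit_factor, x$zone$growth_factor
    ))
  }
  invisible(x)
}

#' @export
as_tibble.stand <- function(x, ...) {
  dplyr::mutate(x$trees, in_sample = in_sample(x))
}

#' Which trees lie in the sampling square?
#'
#' @param stand A [new_stand()] object.
#' @return Logical vector over the stand's trees.
#' @export
in_sample <- function(stand) {
  lo <- stand$sample_origin
  hi <- stand$sample_origin + stand$sample_side
  with(stand$trees, x >= lo & x < hi & y >= lo & y < hi)
}

#' Density, basal area and biomass of the sampling square
#'
#' Summaries are computed over trees inside the inner sampling square only;
#' trees in the edge band never contribute. Basal area is
#' `sum(pi * (dbh/200)^2)` (m2) and biomass the summed allometric tree
#' biomass (t), both divided by the sample area in hectares.
#'
#' Following stand-inventory convention, only stems at or above the census
#' diameter (`min_dbh`, default 5 cm) are counted: the reference densities
#' this simulator is calibrated against census established trees, and the
#' transient sapling bank would otherwise dominate the density. Saplings
#' contribute negligibly to basal area and biomass either way.
#'
#' @param stand A [new_stand()] object.
#' @param params A [species_params()] object (biomass allometry).
#' @param min_dbh Census threshold (cm); stems below it are ignored.
#' @return A one-row tibble: `year`, `n_trees`, `density_ha`,
#'   `basal_area_m2_ha`, `biomass_t_ha`.
#' @examples
#' st <- gen_fixture_stand(density = 500, dbh_mean = 15, dbh_sd = 3, seed = 1)
#' stand_summary(st, species_params())
#' @export
stand_summary <- function(stand, params = species_params(), min_dbh = 5) {
  inside <- stand$trees[in_sample(stand) & stand$trees$dbh >= min_dbh, ]
  area_ha <- (stand$sample_side / 100)^2
  tibble::tibble(
    year = stand$year,
    n_trees = nrow(inside),
    density_ha = nrow(inside) / area_ha,
    basal_area_m2_ha = sum(pi * (inside$dbh / 200)^2) / area_ha,
    biomass_t_ha = sum(tree_biomass(inside$dbh, params)) / 1000 / area_ha
  )
}

#' Write / read a stand snapshot as CSV
#'
#' Columns: `x`, `y`, `dbh_cm`, `age`, `in_sample`. The growth memory is not
#' serialized; a reloaded stand starts with an empty memory.
#'
#' @param stand A stand.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_stand_csv`); a `stand` (`read_stand_csv`).
#' @export
write_stand_csv <- function(stand, path) {
  out <- tibble::tibble(
    x = stand$trees$x, y = stand$trees$y,
    dbh_cm = stand$trees$dbh, age = stand$trees$age,
    in_sample = in_sample(stand)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_stand_csv
#' @param domain_side,sample_origin,sample_side,year Stand geometry for the
#'   reloaded snapshot (see [new_stand()]).
#' @export
read_stand_csv <- function(path, domain_side = 120, sample_origin = 10,
                           sample_side = 100, year = 0) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  new_stand(
    tibble::tibble(x = df$x, y = df$y, dbh = df$dbh_cm, age = df$age),
    domain_side = domain_side, sample_origin = sample_origin,
    sample_side = sample_side, year = year
  )
}
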