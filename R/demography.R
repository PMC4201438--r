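#' Push this year's relative increments into the growth memory
#'
#' Each tree remembers its last five annual relative diameter increments
#' (`ddbh / dbh`, evaluated on the pre-growth diameter); the suppression test
#' in [mortality_step()] uses their moving average. The newest value sits in
#' `m1`, the oldest drops out of `m5`.
#'
#' @param trees The tree tibble of a stand (columns `dbh`, `m1..m5`).
#' @param ddbh Diameter increments (cm) aligned with `trees`.
#' @return The tree tibble with shifted memory.
#' @export
update_growth_memory <- function(trees, ddbh) {
  stopifnot(length(ddbh) == nrow(trees), all(ddbh >= 0))
  if (nrow(trees) == 0) return(trees)
  rel <- ifelse(trees$dbh > 0, ddbh / trees$dbh, 0)
  trees$m5 <- trees$m4
  trees$m4 <- trees$m3
  trees$m3 <- trees$m2
  trees$m2 <- trees$m1
  trees$m1 <- rel
  trees
}

growth_memory_mean <- function(trees) {
  rowMeans(as.matrix(trees[, paste0("m", 1:5)]))
}

#' Suppression-driven (and old-age) mortality
#'
#' A tree whose five-year mean relative increment lies below
#' `suppression_threshold` is suppressed and dies this year with probability
#' `p_die_suppressed`. Trees with fewer than five recorded increments are not
#' yet exposed. If `max_age` is finite, trees beyond it die deterministically
#' (the old-forest correction used for undisturbed control runs).
#'
#' @param stand A [new_stand()] object whose memories were updated this year.
#' @param params A [species_params()] object.
#' @return The stand with dead trees removed.
#' @export
mortality_step <- function(stand, params = species_params()) {
  tr <- stand$trees
  if (nrow(tr) == 0) return(stand)
  mm <- growth_memory_mean(tr)
  suppressed <- !is.na(mm) & mm < params$suppression_threshold
  dies <- suppressed & runif(nrow(tr)) < params$p_die_suppressed
  if (is.finite(params$max_age)) dies <- dies | tr$age > params$max_age
  stand$trees <- tr[!dies, ]
  stand
}

#' Stochastic seedling recruitment
#'
#' Seed dispersal is random: candidate positions fall uniformly over the full
#' domain, their number Poisson with mean `base_rate` (per ha per yr) times
#' the domain area. A candidate inside the impact zone is kept with the
#' zone's recruit factor. It then establishes with probability
#' `max(0, 1 - sum of FON intensities)` at its position, so a closed canopy
#' admits no saplings. Established saplings enter at `recruit_dbh` with an
#' empty growth memory.
#'
#' @param stand A [new_stand()] object.
#' @param params A [species_params()] object.
#' @param base_rate Undisturbed recruitment rate (seedlings per ha per yr).
#' @return The stand with new saplings appended.
#' @export
recruitment_step <- function(stand, params = species_params(),
                             base_rate = 390) {
  stopifnot(base_rate >= 0)
  domain_ha <- (stand$domain_side / 100)^2
  n_cand <- rpois(1, base_rate * domain_ha)
  if (n_cand == 0) return(stand)
  px <- runif(n_cand, 0, stand$domain_side)
  py <- runif(n_cand, 0, stand$domain_side)
  keep <- runif(n_cand) < zone_factor_at(stand, px, "recruit_factor")
  px <- px[keep]; py <- py[keep]
  if (length(px) == 0) return(stand)
  p_est <- pmax(0, 1 - fon_field(stand, px, py, params))
  est <- runif(length(px)) < p_est
  if (!any(est)) return(stand)
  saplings <- tibble::tibble(
    x = px[est], y = py[est], dbh = params$recruit_dbh, age = 0,
    m1 = NA_real_, m2 = NA_real_, m3 = NA_real_, m4 = NA_real_, m5 = NA_real_
  )
  stand$trees <- dplyr::bind_rows(stand$trees, saplings)
  stand
}

# Zone factor (recruit_factor / growth_factor) at x-positions; 1 outside the
# impact strip or when no impact has been applied.
zone_factor_at <- function(stand, x, which) {
  out <- rep(1, length(x))
  z <- stand$zone
  if (!is.null(z)) out[x >= z$x_min & x < z$x_max] <- z[[which]]
  out
}

#' Advance the stand by one year
#'
#' Applies, in order: competition indices for all trees, diameter growth
#' (with zone growth factors), growth-memory update, suppression mortality,
#' recruitment, and ageing. The update is deterministic given the stand and
#' the RNG state.
#'
#' @inheritParams recruitment_step
#' @return The stand one year on.
#' @export
step_year <- function(stand, params = species_params(), base_rate = 390) {
  tr <- stand$trees
  if (nrow(tr) > 0) {
    F <- competition_index(stand, params, cap = 1 / params$comp_slope)
    zf <- zone_factor_at(stand, tr$x, "growth_factor")
    dd <- annual_growth(tr$dbh, F, zf, params)
    tr <- update_growth_memory(tr, dd)
    tr$dbh <- tr$dbh + dd
    stand$trees <- tr
    stand <- mortality_step(stand, params)
  }
  stand <- recruitment_step(stand, params, base_rate)
  stand$trees$age <- stand$trees$age + 1
  stand$year <- stand$year + 1
  stand
}

#' Run the stand forward and record its trajectory
#'
#' @inheritParams recruitment_step
#' @param years Number of annual steps.
#' @param trace_every Record a [stand_summary()] row every so many years
#'   (the final year is always recorded).
#' @return A `sim_result`: list with the final `stand` and a `trajectory`
#'   tibble of summaries.
#' @examples
#' set.seed(1)
#' res <- simulate_years(new_stand(), years = 5, params = species_params())
#' res$trajectory
#' @export
simulate_years <- function(stand, years, params = species_params(),
                           base_rate = 390, trace_every = 1) {
  rows <- vector("list", years)
  for (t in seq_len(years)) {
    stand <- step_year(stand, params, base_rate)
    if (t %% trace_every == 0 || t == years) {
      rows[[t]] <- stand_summary(stand, params)
    }
  }
  structure(
    list(stand = stand, trajectory = dplyr::bind_rows(rows)),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  last <- utils::tail(x$trajectory, 1)
  cat(sprintf(
    "<sim_result> year %d: %d trees, %.1f t/ha, %.1f m2/ha basal area\n",
    x$stand$year, last$n_trees, last$biomass_t_ha, last$basal_area_m2_ha
  ))
  invisible(x)
}
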