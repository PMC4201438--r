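#' Grow a virtual forest from a bare domain to equilibrium
#'
#' Runs the annual update for `years` (default 300) from an empty domain at
#' the undisturbed recruitment rate. The resulting stand is the "healthy
#' forest" snapshot that impact scenarios start from. A warning is raised if
#' the final sample biomass misses the equilibrium target by more than 25%.
#'
#' @param params A [species_params()] object.
#' @param years Spinup length (years).
#' @param base_rate Recruitment rate (seedlings per ha per yr).
#' @param target Equilibrium biomass the spinup should approach (t/ha).
#' @param trace_every Trajectory recording cadence (years).
#' @return A `sim_result` (final stand + trajectory).
#' @examples
#' \donttest{
#' set.seed(42)
#' eq <- spinup(species_params())
#' dplyr::last(eq$trajectory$biomass_t_ha)
#' }
#' @export
spinup <- function(params = species_params(), years = 300, base_rate = 390,
                   target = 375, trace_every = 5) {
  res <- simulate_years(new_stand(), years, params, base_rate, trace_every)
  final <- dplyr::last(res$trajectory$biomass_t_ha)
  if (abs(final - target) > 0.25 * target) {
    warning(sprintf(
      "spinup biomass %.1f t/ha is more than 25%% from the %.0f t/ha target; recalibration advised",
      final, target
    ), call. = FALSE)
  }
  res
}

#' Replicated recovery runs for one impact scenario
#'
#' Applies the impact to the (shared) equilibrium stand and measures the
#' recovery time, once per replicate with replicate-specific RNG substreams
#' derived from `base_seed`. The scenario's summary statistic is the median
#' recovery time; censored replicates enter the median at the censoring
#' horizon and are flagged.
#'
#' @param spec An [impact_spec()].
#' @param stand Equilibrium stand from [spinup()].
#' @param params A [species_params()] object.
#' @param n_reps Number of replicates.
#' @param base_seed Integer seed; replicate r uses seed `base_seed + r`.
#' @param band,max_years,base_rate Passed to [recovery_time()].
#' @param mode Killing mode passed to [apply_impact()].
#' @return An object of class `recovery_result`.
#' @export
run_scenario <- function(spec, stand, params = species_params(),
                         n_reps = 20, base_seed = 1, band = c(300, 400),
                         max_years = 200, base_rate = 390,
                         mode = "clear") {
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    seed <- base_seed + r
    set.seed(seed)
    disturbed <- apply_impact(stand, spec, mode = mode)
    rec <- recovery_time(disturbed, params, band, max_years, base_rate)
    dplyr::mutate(rec, replicate = r, seed = seed, .before = 1)
  })
  structure(
    list(
      impact = spec, replicates = reps,
      median_years = median(reps$years),
      n_reps = n_reps, n_censored = sum(reps$censored),
      band = band, max_years = max_years
    ),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "<recovery_result> %s (I=%.2f, S=%.2f, %s): median %s%g years over %d replicates (%d censored at %d)\n",
    x$impact$name, x$impact$intensity, x$impact$spatial_scale,
    x$impact$formula_mode, if (x$n_censored > x$n_reps / 2) ">=" else "",
    x$median_years, x$n_reps, x$n_censored, x$max_years
  ))
  invisible(x)
}

#' @describeIn run_scenario Broom-style per-replicate tidy output.
#' @param x A `recovery_result`.
#' @param ... Unused.
#' @export
tidy.recovery_result <- function(x, ...) {
  dplyr::mutate(
    x$replicates,
    impact = x$impact$name, intensity = x$impact$intensity,
    spatial_scale = x$impact$spatial_scale,
    formula_mode = x$impact$formula_mode, .before = 1
  )
}

#' @describeIn run_scenario Broom-style one-row scenario summary.
#' @export
glance.recovery_result <- function(x, ...) {
  tibble::tibble(
    impact = x$impact$name,
    intensity = x$impact$intensity,
    spatial_scale = x$impact$spatial_scale,
    formula_mode = x$impact$formula_mode,
    median_years = x$median_years,
    n_reps = x$n_reps,
    n_censored = x$n_censored
  )
}

#' Generic tidiers
#'
#' Broom-style generics for the package's result objects.
#' @param x An object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Run every impact scenario against one equilibrium stand
#'
#' One shared spinup snapshot is reused across all scenarios and replicates
#' (with distinct replicate seeds), isolating impact-response variance from
#' spinup variance.
#'
#' @param impacts A list of [impact_spec()] objects.
#' @param stand Equilibrium stand from [spinup()].
#' @inheritParams run_scenario
#' @return A tibble with one row per impact (the [glance.recovery_result()]
#'   columns) and a `replicates` list-column of per-replicate results.
#' @export
run_all <- function(impacts, stand, params = species_params(), n_reps = 20,
                    base_seed = 1, band = c(300, 400), max_years = 200,
                    base_rate = 390) {
  if (length(impacts) == 0) {
    return(tibble::tibble(
      impact = character(), intensity = numeric(), spatial_scale = numeric(),
      formula_mode = character(), median_years = numeric(),
      n_reps = integer(), n_censored = integer(), replicates = list()
    ))
  }
  results <- purrr::imap(impacts, function(spec, i) {
    run_scenario(spec, stand, params, n_reps,
      base_seed = base_seed + 10000 * (i - 1),
      band = band, max_years = max_years, base_rate = base_rate
    )
  })
  out <- purrr::map_dfr(results, glance)
  out$replicates <- purrr::map(results, "replicates")
  out
}

#' Write replicate recovery records as CSV
#'
#' One row per replicate with columns `scenario`, `replicate`, `seed`,
#' `years`, `censored`. Accepts a single `recovery_result` or the
#' [run_all()] table (all scenarios are concatenated).
#'
#' @param results A `recovery_result` or a [run_all()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recovery_csv <- function(results, path) {
  if (inherits(results, "recovery_result")) {
    long <- tidy(results)
  } else {
    stopifnot(is.data.frame(results), "replicates" %in% names(results))
    long <- tidyr::unnest(results[, c("impact", "replicates")], "replicates")
  }
  out <- tibble::tibble(
    scenario = long$impact, replicate = long$replicate, seed = long$seed,
    years = long$years, censored = long$censored
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Calibrate species parameters against reference-stand anchors
#'
#' Cyclic coordinate search over `g_growth`, `d_max`, `allom_s` and
#' `suppression_threshold`, minimizing the summed squared relative error of
#' the year-`years` sample density, basal area and biomass against the
#' anchors. Each candidate is scored as the mean over `n_seeds` spinups.
#' Deterministic given `base_seed`.
#'
#' @param params Starting [species_params()].
#' @param anchors Named vector: `density` (trees/ha), `basal_area` (m2/ha),
#'   `biomass` (t/ha).
#' @param lower,upper Named bounds for the four searched parameters.
#' @param years Spinup length per evaluation.
#' @param n_seeds Seeds averaged per evaluation.
#' @param n_cycles Coordinate-descent sweeps.
#' @param n_grid Candidate points per parameter per sweep.
#' @param base_seed RNG seed for the evaluation seeds.
#' @param base_rate Recruitment rate.
#' @param tol Mean relative error below which calibration counts as converged.
#' @return List: calibrated `params`, `report` tibble of evaluations,
#'   `loss`, `converged` flag.
#' @export
calibrate <- function(params = species_params(),
                      anchors = c(density = 1344, basal_area = 31.89,
                                  biomass = 375),
                      lower = c(g_growth = 80, d_max = 40, allom_s = 0.1,
                                suppression_threshold = 0.001),
                      upper = c(g_growth = 400, d_max = 110, allom_s = 0.5,
                                suppression_threshold = 0.02),
                      years = 300, n_seeds = 2, n_cycles = 2, n_grid = 5,
                      base_seed = 1, base_rate = 390, tol = 0.25) {
  seeds <- base_seed + seq_len(n_seeds)
  loss_of <- function(p) {
    errs <- purrr::map_dbl(seeds, function(s) {
      set.seed(s)
      res <- suppressWarnings(
        simulate_years(new_stand(), years, p, base_rate, trace_every = years)
      )
      sm <- dplyr::last(res$trajectory)
      sum(
        ((sm$density_ha - anchors["density"]) / anchors["density"])^2,
        ((sm$basal_area_m2_ha - anchors["basal_area"]) / anchors["basal_area"])^2,
        ((sm$biomass_t_ha - anchors["biomass"]) / anchors["biomass"])^2
      )
    })
    mean(errs)
  }
  searched <- names(lower)
  best <- params
  best_loss <- loss_of(best)
  log <- list(tibble::tibble(
    param = "start", value = NA_real_, loss = best_loss
  ))
  for (cycle in seq_len(n_cycles)) {
    for (nm in searched) {
      grid <- seq(lower[[nm]], upper[[nm]], length.out = n_grid)
      for (v in grid) {
        cand <- best
        cand[[nm]] <- v
        cand_loss <- loss_of(cand)
        log <- c(log, list(tibble::tibble(param = nm, value = v,
                                          loss = cand_loss)))
        if (cand_loss < best_loss) {
          best <- cand
          best_loss <- cand_loss
        }
      }
    }
  }
  converged <- sqrt(best_loss / 3) < tol
  if (!converged) {
    warning("calibration did not reach the anchor tolerance; best loss ",
            signif(best_loss, 3), call. = FALSE)
  }
  list(
    params = best, report = dplyr::bind_rows(log),
    loss = best_loss, converged = converged
  )
}
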