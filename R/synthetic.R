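#' Generate a synthetic Likert vote table
#'
#' Emulates ranking-question responses. Each option has a latent quality
#' drawn uniformly on `[0, 1]`; each expert's vote level is a clipped
#' quantile transform of `preference_strength * (quality - 0.5)` plus
#' standard logistic noise, so at `preference_strength = 0` the level counts
#' are exactly uniform and larger strengths shift each option's modal level
#' towards its quality. Pure function of `seed`.
#'
#' @param n_options,n_experts Numbers of options and of experts (each votes
#'   once per option).
#' @param preference_strength Nonnegative scale of the quality signal.
#' @param seed Integer seed.
#' @return A vote table: tibble with `option`, `quality` and counts `l1..l5`
#'   whose rows each sum to `n_experts`.
#' @export
gen_vote_table <- function(n_options, n_experts, preference_strength = 2,
                           seed = 1) {
  stopifnot(n_options >= 1, n_experts >= 1, preference_strength >= 0)
  withr_seed(seed)
  quality <- runif(n_options)
  counts <- t(vapply(quality, function(q) {
    latent <- preference_strength * (q - 0.5) + rlogis(n_experts)
    lev <- pmin(5, pmax(1, ceiling(5 * plogis(latent))))
    tabulate(lev, nbins = 5)
  }, integer(5)))
  out <- tibble::tibble(
    option = sprintf("option_%02d", seq_len(n_options)),
    quality = quality
  )
  for (k in 1:5) out[[paste0("l", k)]] <- counts[, k]
  out
}

#' Generate a synthetic impact set
#'
#' Emulates an expert-elicited set of (intensity, spatial scale) scores on
#' the unit square for the ten canonical mangrove impacts. With
#' `make_dominant` the `development` impact receives the componentwise
#' maximum of all drawn intensities and scales, mirroring its elicited
#' dominance. Pure function of `seed`.
#'
#' @param n_impacts Number of impacts (names recycle beyond ten).
#' @param seed Integer seed.
#' @param make_dominant Give `development` the componentwise maximum scores.
#' @param formula_mode Passed to [impact_spec()].
#' @return A list of [impact_spec()] objects.
#' @export
gen_impact_set <- function(n_impacts = 10, seed = 1, make_dominant = TRUE,
                           formula_mode = "literal") {
  stopifnot(n_impacts >= 1)
  withr_seed(seed)
  nm <- rep_len(impact_names(), n_impacts)
  if (n_impacts <= length(impact_names())) nm <- impact_names()[seq_len(n_impacts)]
  I <- runif(n_impacts, 0.2, 0.9)
  S <- runif(n_impacts, 0.2, 0.9)
  if (make_dominant) {
    i_dev <- match("development", nm)
    if (is.na(i_dev)) i_dev <- 1L
    I[i_dev] <- max(I)
    S[i_dev] <- max(S)
  }
  purrr::pmap(list(nm, I, S), impact_spec, formula_mode = formula_mode)
}

#' The ten canonical impact labels
#' @return Character vector of length 10.
#' @export
impact_names <- function() {
  c(
    "development", "tourism", "household uses", "aquaculture",
    "natural disasters", "climate change", "pests/disease",
    "extractive processes", "pollution", "war"
  )
}

#' Generate synthetic recovery-timeframe responses
#'
#' Emulates per-expert recovery-time votes: one of the four timeframe bins,
#' a country drawn from `country_pool`, and a restoration mode. Pure
#' function of `seed`.
#'
#' @param n_experts Number of responses.
#' @param country_pool Countries to sample from (default: the bundled HDI
#'   roster).
#' @param bin_probs Probabilities over [timeframe_bins()]; must sum to 1.
#' @param seed Integer seed.
#' @return A tibble: `expert`, `country`, `mode`, `bin`.
#' @export
gen_timeframe_responses <- function(n_experts,
                                    country_pool = hdi_countries()$country,
                                    bin_probs = c(0.25, 0.25, 0.25, 0.25),
                                    seed = 1) {
  stopifnot(n_experts >= 1, length(bin_probs) == 4,
            abs(sum(bin_probs) - 1) < 1e-8, all(bin_probs >= 0))
  withr_seed(seed)
  tibble::tibble(
    expert = sprintf("expert_%03d", seq_len(n_experts)),
    country = sample(country_pool, n_experts, replace = TRUE),
    mode = sample(c("natural", "human-assisted"), n_experts, replace = TRUE),
    bin = sample(timeframe_bins(), n_experts, replace = TRUE,
                 prob = bin_probs)
  )
}

#' Generate a synthetic fixture stand
#'
#' Scatters a Poisson number of trees (at the given density) uniformly over
#' the domain with truncated-normal diameters; ages default to 0 and growth
#' memories start empty. Pure function of `seed`.
#'
#' @param density Trees per hectare over the whole domain.
#' @param dbh_mean,dbh_sd Diameter distribution (cm); draws are truncated to
#'   `(0, d_max]`.
#' @param seed Integer seed.
#' @param params A [species_params()] object (for `d_max`).
#' @param domain_side,sample_origin,sample_side Stand geometry.
#' @return A [new_stand()] object.
#' @export
gen_fixture_stand <- function(density, dbh_mean = 17.4, dbh_sd = 3,
                              seed = 1, params = species_params(),
                              domain_side = 120, sample_origin = 10,
                              sample_side = 100) {
  stopifnot(density >= 0, dbh_mean > 0, dbh_sd >= 0)
  withr_seed(seed)
  n <- rpois(1, density * (domain_side / 100)^2)
  if (n == 0) {
    return(new_stand(NULL, domain_side, sample_origin, sample_side))
  }
  dbh <- rnorm(n, dbh_mean, dbh_sd)
  while (any(bad <- dbh <= 0 | dbh > params$d_max)) {
    dbh[bad] <- rnorm(sum(bad), dbh_mean, dbh_sd)
  }
  new_stand(
    tibble::tibble(
      x = runif(n, 0, domain_side), y = runif(n, 0, domain_side), dbh = dbh
    ),
    domain_side, sample_origin, sample_side
  )
}

# Generators are pure functions of their seed.
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}
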