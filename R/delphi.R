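#' Weighted Likert ranking of survey options
#'
#' Each Likert level (1-5) is weighted by its own value and multiplied by the
#' number of votes it received; an option's weighted score is the sum over
#' levels. Scores are expressed on a percentage scale. The default
#' normalization (`"max_attainable"`) divides by the maximum attainable score,
#' `5 *` the option's vote count, so 100% means a unanimous top rating and
#' the floor is 20% (everyone votes 1). The alternative (`"share"`) expresses
#' each score as a share of the summed scores across options.
#'
#' @param votes A data frame with an option identifier column (the first
#'   non-count column, typically `option`) and count columns `l1`..`l5`.
#' @param normalization `"max_attainable"` (default) or `"share"`.
#' @return A tibble sorted by descending percentage: `option`, `n_votes`,
#'   `score`, `pct`, `rank`, `tied`. Options with zero votes get `NA`
#'   percentages and sort last. Ties share the minimum rank, are broken
#'   alphabetically in the row order, and are flagged.
#' @examples
#' votes <- tibble::tibble(option = c("a", "b"),
#'                         l1 = c(1, 0), l2 = c(2, 0), l3 = c(3, 0),
#'                         l4 = c(4, 0), l5 = c(5, 10))
#' weighted_likert_scores(votes)
#' @export
weighted_likert_scores <- function(votes,
                                   normalization = c("max_attainable",
                                                     "share")) {
  normalization <- match.arg(normalization)
  lev_cols <- paste0("l", 1:5)
  stopifnot(all(lev_cols %in% names(votes)))
  counts <- as.matrix(votes[, lev_cols])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("vote counts must be nonnegative integers", call. = FALSE)
  }
  id_col <- setdiff(names(votes), lev_cols)[1]
  n_votes <- rowSums(counts)
  score <- as.numeric(counts %*% (1:5))
  pct <- switch(normalization,
    max_attainable = ifelse(n_votes > 0, 100 * score / (5 * n_votes),
                            NA_real_),
    share = if (sum(score) > 0) 100 * score / sum(score) else
      rep(NA_real_, length(score))
  )
  out <- tibble::tibble(
    option = as.character(votes[[id_col]]),
    n_votes = n_votes, score = score, pct = pct
  )
  out <- dplyr::arrange(out, dplyr::desc(!is.na(.data$pct)),
                        dplyr::desc(.data$pct), .data$option)
  out$rank <- rank(-out$pct, ties.method = "min", na.last = "keep")
  out$tied <- !is.na(out$pct) & duplicated(out$pct) |
    !is.na(out$pct) & duplicated(out$pct, fromLast = TRUE)
  out
}

#' Consensus listing by a strict vote-share threshold
#'
#' Items are included when strictly more than `threshold` percent of experts
#' voted for them; an item at exactly the threshold is excluded. Input order
#' is preserved.
#'
#' @param vote_fractions A data frame whose first column identifies the item
#'   (e.g. `species`) and that has a `pct_yes` column in `[0, 100]`.
#' @param threshold Inclusion threshold (percent).
#' @return The subset of rows above the threshold.
#' @examples
#' consensus_list(tibble::tibble(species = c("a", "b"), pct_yes = c(54, 50)))
#' @export
consensus_list <- function(vote_fractions, threshold = 50) {
  stopifnot("pct_yes" %in% names(vote_fractions))
  pct <- vote_fractions$pct_yes
  if (any(pct < 0 | pct > 100)) {
    stop("pct_yes must lie in [0, 100]", call. = FALSE)
  }
  vote_fractions[pct > threshold, , drop = FALSE]
}

#' Plurality winner among candidates
#'
#' Returns the candidate with the most votes; ties are reported, never
#' silently broken, and an all-zero count yields no winner.
#'
#' @param counts A data frame with columns `candidate` and `votes`, or a
#'   named numeric vector.
#' @return A list: `winner` (character, `NA` if no votes or tied), `tied`
#'   (logical), `tied_candidates` (character vector).
#' @examples
#' plurality_choice(c(natural = 7, assisted = 13))
#' @export
plurality_choice <- function(counts) {
  if (is.data.frame(counts)) {
    cand <- as.character(counts$candidate)
    v <- counts$votes
  } else {
    cand <- names(counts)
    v <- as.numeric(counts)
  }
  stopifnot(length(v) >= 1, all(v >= 0))
  if (all(v == 0)) {
    return(list(winner = NA_character_, tied = FALSE,
                tied_candidates = character()))
  }
  top <- which(v == max(v))
  if (length(top) > 1) {
    list(winner = NA_character_, tied = TRUE, tied_candidates = cand[top])
  } else {
    list(winner = cand[top], tied = FALSE, tied_candidates = character())
  }
}

#' The four recovery timeframe bins
#'
#' Expert responses on recovery time use four bins; the first two aggregate
#' to "short" (< 20 years), the last two to "long" (> 20 years).
#' @return Character vector of bin labels.
#' @export
timeframe_bins <- function() c("0-10", "10-20", "20-30", ">30")

#' Stratified counts of recovery-timeframe responses
#'
#' Collapses the four timeframe bins to short term (< 20 years: bins 0-10 and
#' 10-20) and long term (> 20 years: bins 20-30 and >30), and stratifies by
#' the development level (HD = highly developed, LD = less developed, per the
#' Human Development Index classification) of the country each expert
#' reported on, and by restoration mode.
#'
#' @param responses A data frame with columns `expert`, `country`, `mode`
#'   (`"natural"` or `"human-assisted"`) and `bin` (one of
#'   [timeframe_bins()]).
#' @param hdi_map A data frame with columns `country` and `level`
#'   (`"HD"`/`"LD"`); defaults to the bundled classification, see
#'   [hdi_countries()].
#' @return A tibble of counts over the full `level` x `term` x `mode` grid
#'   (zero-filled): columns `level`, `term`, `mode`, `n`.
#' @export
aggregate_timeframes <- function(responses, hdi_map = hdi_countries()) {
  stopifnot(all(c("expert", "country", "mode", "bin") %in% names(responses)))
  bad_bin <- setdiff(unique(responses$bin), timeframe_bins())
  if (length(bad_bin) > 0) {
    stop("unknown timeframe bin(s): ", paste(bad_bin, collapse = ", "),
         call. = FALSE)
  }
  unmapped <- setdiff(unique(responses$country), hdi_map$country)
  if (length(unmapped) > 0) {
    stop("countries missing from the HDI map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  responses |>
    dplyr::left_join(hdi_map[, c("country", "level")], by = "country") |>
    dplyr::mutate(
      term = ifelse(.data$bin %in% c("0-10", "10-20"), "short", "long")
    ) |>
    dplyr::count(.data$level, .data$term, .data$mode) |>
    tidyr::complete(
      level = sort(unique(hdi_map$level)),
      term = c("short", "long"),
      mode = sort(unique(responses$mode)),
      fill = list(n = 0L)
    )
}

#' Bundled HD/LD country classification
#'
#' The countries where surveyed experts did the bulk of their fieldwork,
#' classified as highly developed (HD: HDI categories "very high" and "high")
#' or less developed (LD: "medium" and "low") under the 2011 Human
#' Development Index, with the number of expert responses per country.
#' Shipped as an editable CSV in `extdata`.
#'
#' @return A tibble: `country`, `level`, `n_responses`.
#' @examples
#' dplyr::count(hdi_countries(), level, wt = n_responses)
#' @export
hdi_countries <- function() {
  readr::read_csv(
    system.file("extdata", "hdi_countries.csv", package = "mangrovesim"),
    show_col_types = FALSE
  )
}

#' Bundled consensus vote shares for mangrove plant species
#'
#' Percentage of first-round experts voting each plant species a true
#' mangrove, for the species that cleared the strict >50% consensus rule.
#'
#' @return A tibble: `species`, `pct_yes`.
#' @export
species_votes <- function() {
  readr::read_csv(
    system.file("extdata", "species_votes.csv", package = "mangrovesim"),
    show_col_types = FALSE
  )
}

#' Round-to-round participant retention
#'
#' Percentage of participants retained between survey rounds, rounded to the
#' whole percent conventionally reported.
#'
#' @param n_returned Participants in the later round.
#' @param n_invited Participants (or invitees) in the earlier round.
#' @return Retention percentage (integer-valued double).
#' @examples
#' retention_pct(19, 35) # 54
#' @export
retention_pct <- function(n_returned, n_invited) {
  stopifnot(n_invited > 0, n_returned >= 0)
  round(100 * n_returned / n_invited)
}
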