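# Independent plain-R oracles, deliberately separate from the package's
# C++ code path.

# FON intensity of a single stem at points (px, py).
oracle_intensity <- function(x, y, dbh, px, py, p) {
  if (dbh <= 0) return(rep(0, length(px)))
  rs <- dbh / 200
  R <- max(p$fon_a * rs^p$fon_b, rs)
  d <- sqrt((px - x)^2 + (py - y)^2)
  out <- ifelse(d <= rs, 1,
    ifelse(d <= R & R > rs, exp(log(p$fon_min) * (d - rs) / (R - rs)), 0)
  )
  out
}

# Brute-force fine-grid competition index of tree i: mean over the focal FON
# disc of the summed neighbour intensities.
oracle_competition <- function(trees, i, p, h = 0.02) {
  rs <- trees$dbh[i] / 200
  R <- max(p$fon_a * rs^p$fon_b, rs)
  if (R <= 0) return(0)
  g <- seq(-R + h / 2, R, by = h)
  px <- rep(trees$x[i] + g, times = length(g))
  py <- rep(trees$y[i] + g, each = length(g))
  keep <- (px - trees$x[i])^2 + (py - trees$y[i])^2 <= R^2
  px <- px[keep]; py <- py[keep]
  s <- rep(0, length(px))
  for (j in seq_len(nrow(trees))) {
    if (j == i) next
    s <- s + oracle_intensity(trees$x[j], trees$y[j], trees$dbh[j], px, py, p)
  }
  mean(s)
}

# Fast, small test parameterization: tiny domain keeps unit tests cheap.
test_params <- function(...) species_params(...)

small_stand <- function(trees, side = 40, origin = 5, sample = 30) {
  new_stand(trees, domain_side = side, sample_origin = origin,
            sample_side = sample)
}
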