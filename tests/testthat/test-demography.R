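make_trees <- function(n = 1, dbh = 10) {
  tibble::tibble(
    x = seq_len(n) * 3, y = rep(5, n), dbh = dbh, age = 0,
    m1 = NA_real_, m2 = NA_real_, m3 = NA_real_, m4 = NA_real_, m5 = NA_real_
  )
}

test_that("growth memory is a 5-slot ring buffer of relative increments", {
  tr <- make_trees(1, dbh = 10)
  # push 6 distinct increments; the first must have been evicted
  incs <- c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  for (i in incs) tr <- update_growth_memory(tr, i)
  mem <- unlist(tr[1, paste0("m", 1:5)], use.names = FALSE)
  expect_equal(mem, rev(incs[-1]) / 10)
  # constant relative increment r pushed 5x -> moving average r
  tr2 <- make_trees(1, dbh = 20)
  for (k in 1:5) tr2 <- update_growth_memory(tr2, 20 * 0.03)
  expect_equal(mean(unlist(tr2[1, paste0("m", 1:5)])), 0.03)
  # increments (0.1, 0, 0, 0, 0) relative -> mean 0.02
  tr3 <- make_trees(1, dbh = 1)
  for (v in c(0.1, 0, 0, 0, 0)) tr3 <- update_growth_memory(tr3, v)
  expect_equal(mean(unlist(tr3[1, paste0("m", 1:5)])), 0.02)
})

test_that("suppression mortality spares the vigorous and the unexposed", {
  p <- species_params(suppression_threshold = 0.01, p_die_suppressed = 1)
  # all above threshold: unchanged
  tr <- make_trees(5, dbh = 10)
  for (k in 1:5) tr <- update_growth_memory(tr, rep(0.5, 5))
  st <- small_stand(tr)
  set.seed(1)
  expect_equal(nrow(mortality_step(st, p)$trees), 5)
  # suppressed with p = 1: removed deterministically
  tr2 <- make_trees(5, dbh = 10)
  for (k in 1:5) tr2 <- update_growth_memory(tr2, rep(0, 5))
  st2 <- small_stand(tr2)
  set.seed(1)
  expect_equal(nrow(mortality_step(st2, p)$trees), 0)
  # empty memory (young sapling): not yet exposed
  st3 <- small_stand(make_trees(5, dbh = 10))
  set.seed(1)
  expect_equal(nrow(mortality_step(st3, p)$trees), 5)
})

test_that("suppressed trees die at the binomial rate", {
  p <- species_params(suppression_threshold = 0.01, p_die_suppressed = 0.3)
  tr <- tibble::tibble(
    x = runif(100, 0, 40), y = runif(100, 0, 40), dbh = 10, age = 0,
    m1 = 0, m2 = 0, m3 = 0, m4 = 0, m5 = 0
  )
  survivors <- vapply(1:40, function(s) {
    set.seed(s)
    nrow(mortality_step(small_stand(tr), p)$trees)
  }, numeric(1))
  # mean survivors over seeds within 99% normal bounds of Binomial(100, 0.7)
  se <- sqrt(100 * 0.3 * 0.7 / 40)
  expect_lt(abs(mean(survivors) - 70), 2.58 * se)
})

test_that("old-age cap removes trees beyond max_age", {
  p <- species_params(max_age = 50, p_die_suppressed = 0)
  tr <- make_trees(3, dbh = 10)
  tr$age <- c(10, 50, 51)
  set.seed(1)
  out <- mortality_step(small_stand(tr), p)
  expect_equal(out$trees$age, c(10, 50))
})

test_that("recruitment: expectation on an empty domain, zero under closed canopy", {
  p <- species_params()
  # empty 1.44 ha domain at 390/ha/yr: ~561.6 recruits, all establish
  n_rec <- vapply(1:20, function(s) {
    set.seed(s)
    nrow(recruitment_step(new_stand(), p, base_rate = 390)$trees)
  }, numeric(1))
  expect_equal(mean(n_rec), 390 * 1.44, tolerance = 0.03)
  # a point under a canopy with summed intensity >= 1 cannot establish:
  # pack the small domain with overlapping large stems
  dense <- tibble::tibble(
    x = rep(seq(1, 39, by = 2), times = 20),
    y = rep(seq(1, 39, by = 2), each = 20),
    dbh = 60
  )
  st <- small_stand(dense)
  set.seed(3)
  expect_true(all(fon_field(st, runif(100, 0, 40), runif(100, 0, 40), p) >= 1))
  set.seed(2)
  expect_equal(nrow(recruitment_step(st, p)$trees), nrow(dense))
})

test_that("a zero recruit factor shuts recruitment inside the zone only", {
  p <- species_params()
  st <- new_stand()
  # total impact over 60% of the hectare: recruit factor 0 in the strip
  st <- apply_impact(st, impact_spec("x", 1, 0, formula_mode = "zone_intensity"))
  st$zone$x_max <- 70 # strip [10, 70)
  set.seed(4)
  out <- recruitment_step(st, p, base_rate = 390)
  expect_equal(sum(out$trees$x >= 10 & out$trees$x < 70), 0)
  expect_gt(sum(out$trees$x < 10 | out$trees$x >= 70), 0)
})

test_that("step_year orchestration: determinism, bookkeeping, growth", {
  p <- species_params()
  # empty stand, no recruitment: still empty, year advances
  set.seed(1)
  out <- step_year(new_stand(), p, base_rate = 0)
  expect_equal(nrow(out$trees), 0)
  expect_equal(out$year, 1)
  # same seed, same stand -> identical successor
  st <- gen_fixture_stand(300, 15, 3, seed = 5)
  set.seed(99); a <- step_year(st, p)
  set.seed(99); b <- step_year(st, p)
  expect_identical(a, b)
  # an isolated tree with no recruitment grows strictly until d_max
  iso <- small_stand(tibble::tibble(x = 20, y = 20, dbh = 5))
  d_path <- numeric(30)
  set.seed(1)
  for (t in 1:30) {
    iso <- step_year(iso, p, base_rate = 0)
    d_path[t] <- iso$trees$dbh
  }
  expect_true(all(diff(c(5, d_path)) > 0))
  expect_equal(iso$trees$age, 30)
})

test_that("tree count only changes through mortality and recruitment", {
  p <- species_params(p_die_suppressed = 0, max_age = Inf)
  st <- gen_fixture_stand(400, 12, 3, seed = 8)
  n0 <- nrow(st$trees)
  set.seed(3)
  out <- step_year(st, p, base_rate = 0) # both channels off
  expect_equal(nrow(out$trees), n0)
})

test_that("without mortality or recruitment, basal area never decreases", {
  p <- species_params(suppression_threshold = 0, p_die_suppressed = 0)
  st <- gen_fixture_stand(600, 12, 4, seed = 9)
  ba <- stand_summary(st, p)$basal_area_m2_ha
  set.seed(2)
  for (t in 1:10) {
    st <- step_year(st, p, base_rate = 0)
    ba2 <- stand_summary(st, p)$basal_area_m2_ha
    expect_gte(ba2, ba)
    ba <- ba2
  }
})
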