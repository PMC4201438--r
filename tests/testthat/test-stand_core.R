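test_that("FON radius follows the stem-radius power law", {
  p <- species_params(fon_a = 10, fon_b = 0.5)
  expect_equal(fon_radius(0, p), 0)
  # r_stem = 18/200 = 0.09 m -> 10 * 0.09^0.5 = 3 m
  expect_equal(fon_radius(18, p), 3)
  # degenerate exponent: every tree gets radius fon_a
  p0 <- species_params(fon_a = 4, fon_b = 0)
  expect_equal(fon_radius(c(2, 18, 60), p0), rep(4, 3))
  # monotone nondecreasing, never below the stem radius
  r <- fon_radius(seq(0.5, 70, by = 0.5), p)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= seq(0.5, 70, by = 0.5) / 200))
  expect_error(fon_radius(-1, p), "nonnegative")
})

test_that("FON intensity: plateau, boundary decay value, compact support", {
  p <- species_params(fon_a = 10, fon_b = 0.5, fon_min = 0.1)
  tree <- list(x = 0, y = 0, dbh = 18)
  R <- fon_radius(18, p)
  expect_equal(fon_intensity(tree, 0, 0, p), 1)           # stem centre
  expect_equal(fon_intensity(tree, 0.05, 0, p), 1)        # inside stem disc
  expect_equal(fon_intensity(tree, R, 0, p), 0.1)         # boundary = fon_min
  expect_equal(fon_intensity(tree, 10 * R, 0, p), 0)      # outside support
  # everywhere in [0, 1], and matches the plain-R oracle
  px <- seq(-4, 4, by = 0.13)
  v <- fon_intensity(tree, px, rep(0.3, length(px)), p)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(v, oracle_intensity(0, 0, 18, px, rep(0.3, length(px)), p),
               tolerance = 1e-12)
})

test_that("competition index matches a fine-grid brute-force oracle within 1%", {
  p <- species_params()
  configs <- list(
    tibble::tibble(x = c(20, 22), y = c(20, 20), dbh = c(20, 20)),
    tibble::tibble(x = c(20, 21, 22), y = c(20, 21, 20), dbh = c(15, 25, 10)),
    tibble::tibble(
      x = c(18, 20, 22, 21, 19), y = c(20, 18, 20, 22, 21),
      dbh = c(30, 12, 18, 25, 8)
    )
  )
  for (trees in configs) {
    st <- small_stand(trees)
    F <- competition_index(st, p)
    for (i in seq_len(nrow(trees))) {
      expect_equal(F[i], oracle_competition(trees, i, p),
                   tolerance = 0.01)
    }
  }
})

test_that("competition index: no neighbours and disjoint FONs give zero", {
  p <- species_params()
  expect_equal(
    competition_index(small_stand(tibble::tibble(x = 20, y = 20, dbh = 20)), p),
    0
  )
  # two identical trees far apart: FONs disjoint
  far <- small_stand(tibble::tibble(x = c(5, 35), y = c(20, 20), dbh = c(20, 20)))
  expect_equal(competition_index(far, p), c(0, 0))
  # two identical overlapping trees: symmetric index
  near <- small_stand(tibble::tibble(x = c(19, 21), y = c(20, 20), dbh = c(20, 20)))
  F <- competition_index(near, p)
  expect_gt(F[1], 0)
  expect_equal(F[1], F[2], tolerance = 1e-10)
})

test_that("height allometry hits its anchors and is monotone", {
  p <- species_params(d_max = 70, h_max = 5000)
  expect_equal(height_from_dbh(0, p), 137)
  expect_equal(height_from_dbh(p$d_max, p), 5000)
  expect_equal(height_from_dbh(p$d_max / 2, p), 137 + 0.75 * (5000 - 137))
  d <- seq(0, p$d_max, length.out = 200)
  expect_true(all(diff(height_from_dbh(d, p)) > 0))
  expect_error(height_from_dbh(p$d_max + 1, p), "d_max")
})

test_that("biomass allometry: zero at zero, linear in allom_s, Matang-consistent", {
  p <- species_params()
  expect_equal(tree_biomass(0, p), 0)
  # 1344 stems at the mean reference diameter carry ~300 t/ha
  expect_equal(1344 * tree_biomass(17.4, p) / 1000, 300, tolerance = 0.02)
  p2 <- species_params(allom_s = 2 * p$allom_s)
  expect_equal(tree_biomass(23, p2), 2 * tree_biomass(23, p))
  expect_true(all(diff(tree_biomass(seq(0, 70, by = 1), p)) > 0))
})

test_that("annual growth: competition floor, asymptote, zone shutdown", {
  p <- species_params()
  expect_equal(annual_growth(20, F = 1 / p$comp_slope, params = p), 0)
  expect_equal(annual_growth(20, F = 5, params = p), 0)
  expect_equal(annual_growth(p$d_max, F = 0, params = p), 0)
  # zone factor from a total impact (I=1, S=0, literal mode) is 0: no growth
  f <- zone_modifiers(impact_spec("x", 1, 0))$growth_factor
  expect_equal(f, 0)
  expect_equal(annual_growth(20, F = 0, zone_growth_factor = f, params = p), 0)
  expect_gt(annual_growth(20, F = 0, params = p), 0)
})

test_that("zero-competition growth converges monotonically to d_max", {
  p <- species_params()
  d <- 1
  path <- numeric(1500)
  for (t in seq_along(path)) {
    d <- d + annual_growth(d, F = 0, params = p)
    path[t] <- d
  }
  expect_true(all(diff(path) >= 0))
  expect_equal(path[length(path)], p$d_max, tolerance = 1e-3)
})

test_that("stand summaries census the inner sample square only", {
  p <- species_params()
  empty <- new_stand()
  expect_equal(
    unlist(stand_summary(empty, p)[, c("n_trees", "basal_area_m2_ha", "biomass_t_ha")]),
    c(n_trees = 0, basal_area_m2_ha = 0, biomass_t_ha = 0)
  )
  # 1344 identical stems at the reference diameter reproduce the basal area
  set.seed(7)
  trees <- tibble::tibble(
    x = runif(1344, 10, 110), y = runif(1344, 10, 110), dbh = 17.38
  )
  st <- new_stand(trees)
  expect_equal(stand_summary(st, p)$basal_area_m2_ha,
               1344 * pi * (17.38 / 200)^2, tolerance = 1e-10)
  expect_equal(stand_summary(st, p)$basal_area_m2_ha, 31.89, tolerance = 0.01)
  # a tree in the 10 m edge band is excluded from all summaries
  st_band <- new_stand(dplyr::bind_rows(trees, tibble::tibble(x = 5, y = 60, dbh = 50)))
  expect_equal(stand_summary(st_band, p), stand_summary(st, p))
  # below-census saplings are not counted
  st_sap <- new_stand(dplyr::bind_rows(trees, tibble::tibble(x = 60, y = 60, dbh = 1)))
  expect_equal(stand_summary(st_sap, p)$n_trees, 1344)
})

test_that("stand summaries are additive over disjoint tree subsets", {
  p <- species_params()
  set.seed(11)
  a <- tibble::tibble(x = runif(40, 0, 120), y = runif(40, 0, 120),
                      dbh = runif(40, 5, 40))
  b <- tibble::tibble(x = runif(25, 0, 120), y = runif(25, 0, 120),
                      dbh = runif(25, 5, 40))
  s_ab <- stand_summary(new_stand(dplyr::bind_rows(a, b)), p)
  s_a <- stand_summary(new_stand(a), p)
  s_b <- stand_summary(new_stand(b), p)
  for (col in c("n_trees", "density_ha", "basal_area_m2_ha", "biomass_t_ha")) {
    expect_equal(s_ab[[col]], s_a[[col]] + s_b[[col]])
  }
})

test_that("stand snapshots round-trip through CSV", {
  st <- gen_fixture_stand(200, 15, 3, seed = 3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_stand_csv(st, path)
  back <- read_stand_csv(path)
  expect_equal(back$trees$x, st$trees$x)
  expect_equal(back$trees$dbh, st$trees$dbh)
  expect_equal(stand_summary(back), stand_summary(st))
})
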