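test_that("the LBG is the masked row mean, with empty rows flagged NA", {
  set.seed(11)
  w <- random_toy_world(6, 6)
  mask <- shelf_mask(w, 1)
  pool <- random_toy_pool(10)
  map <- richness_map(pool, w, mask)
  prof <- lbg(map)
  for (i in 1:6) {
    sel <- mask$cells[i, ]
    if (any(sel)) expect_equal(prof$value[i], mean(map$values[i, sel]))
    else expect_true(is.na(prof$value[i]))
  }
  # constant maps give a constant profile
  map$values[mask$cells] <- 3.5
  expect_true(all(lbg(map)$value[rowSums(mask$cells) > 0] == 3.5))
})

test_that("LCI counts occupied shelf cells and is bounded by the mask", {
  set.seed(22)
  for (rep in 1:20) {
    w <- random_toy_world(8, 8)
    mask <- shelf_mask(w, 2)
    pool <- random_toy_pool(6)
    cube <- annual_occupancy(pool, w, mask)
    got <- lci(cube)
    oracle <- sum(colSums(cube$occupancy) > 0)
    expect_identical(got, as.integer(oracle))
    expect_lte(got, sum(mask$cells))
    # cell-month reading sums monthly occupied counts
    ms_sum <- 0L
    for (m in 1:12) ms_sum <- ms_sum + sum(cube$monthly_presence[, m])
    expect_identical(lci(cube, "sum"), as.integer(ms_sum))
  }
})

test_that("LBG-weighted LCI equals the hand-computed latitudinal sum", {
  set.seed(33)
  w <- random_toy_world(8, 10)
  mask <- shelf_mask(w, 2)
  pool <- random_toy_pool(8)
  cube <- annual_occupancy(pool, w, mask)
  map <- richness_map(pool, w, mask)
  prof <- lbg(map)
  got <- lbg_weighted_lci(cube, prof)
  hand <- 0
  occ_cells <- cube$cells[colSums(cube$occupancy) > 0]
  for (i in 1:8) {
    row_cells <- occ_cells[((occ_cells - 1) %% 8) + 1 == i]
    if (length(row_cells) && !is.na(prof$value[i]))
      hand <- hand + length(row_cells) * prof$value[i]
  }
  expect_equal(got, hand)
  # uniform unit LBG reduces the weighted index to the LCI
  unit <- prof; unit$value[!is.na(unit$value)] <- 1
  expect_equal(lbg_weighted_lci(cube, unit), lci(cube))
  # zero profile kills the index
  zero <- prof; zero$value[] <- 0
  expect_equal(lbg_weighted_lci(cube, zero), 0)
})

test_that("temperature density tallies cell-month samples into 1 C bins", {
  g <- grid_spec(10, 10)
  w <- make_world(world_config(equator_sst = 20, pole_sst = 20,
                               seasonal_amplitude = 0,
                               continents = list(continent(c(-10, 10),
                                                           c(0, 40)))), g)
  mask <- shelf_mask(w)
  d <- temperature_density(w, mask)
  expect_identical(sum(d$counts), sum(mask$cells) * 12L)
  expect_identical(d$modal_bin, 20)
  expect_equal(d$mean_sst, 20)
  # direct tally oracle on a random world
  set.seed(44)
  wr <- random_toy_world(6, 8)
  mr <- shelf_mask(wr, 2)
  dr <- temperature_density(wr, mr)
  samples <- c()
  for (m in 1:12) samples <- c(samples, wr$sst[, , m][mr$cells])
  for (b in seq_along(dr$counts)) {
    lo <- dr$breaks[b]; hi <- dr$breaks[b + 1]
    expect_identical(dr$counts[b], sum(samples >= lo & samples < hi))
  }
  expect_equal(dr$mean_sst, mean(samples))
})

test_that("an empty mask gives an empty histogram", {
  w <- make_world(world_config(), grid_spec(8, 8))
  suppressWarnings(mask <- shelf_mask(w))
  d <- temperature_density(w, mask)
  expect_identical(sum(d$counts), 0L)
  expect_true(is.na(d$modal_bin) && is.na(d$mean_sst))
})

test_that("interpolation reproduces knots and preserves monotone shape", {
  s <- age_series(c(500, 400, 300, 200, 100), c(1, 2, 5, 6, 9))
  at_knots <- interpolate_to_ages(s, s$ages)
  expect_equal(at_knots$values, s$values, tolerance = 1e-12)
  dense <- interpolate_to_ages(s, seq(500, 100, by = -2))
  expect_true(all(diff(dense$values) > 0))    # values rise toward the present
  expect_true(all(dense$values >= 1 & dense$values <= 9))
  expect_error(interpolate_to_ages(s, c(600, 400)), "span")
  expect_error(interpolate_to_ages(s, c(400, 50)), "span")
})

test_that("interpolation matches an independent shape-preserving oracle", {
  set.seed(55)
  for (rep in 1:10) {
    x <- sort(runif(8, 0, 100))
    y <- cumsum(rnorm(8))
    xout <- sort(runif(40, min(x), max(x)))
    s <- age_series(rev(x), rev(y))   # stored old -> young
    got <- interpolate_to_ages(s, rev(xout))
    expect_equal(rev(got$values), pchip_oracle(x, y, xout),
                 tolerance = 1e-10)
  }
})

test_that("indices are invariant under longitude rotation of the world", {
  set.seed(66)
  w <- random_toy_world(8, 10)
  pool <- random_toy_pool(8)
  wr <- rotate_world(w, 3)
  cube <- annual_occupancy(pool, w, shelf_mask(w, 2))
  cube_r <- annual_occupancy(pool, wr, shelf_mask(wr, 2))
  expect_identical(lci(cube), lci(cube_r))
  map <- richness_map(pool, w, shelf_mask(w, 2))
  map_r <- richness_map(pool, wr, shelf_mask(wr, 2))
  expect_equal(lbg(map)$value, lbg(map_r)$value)
  expect_equal(lbg_weighted_lci(cube, lbg(map)),
               lbg_weighted_lci(cube_r, lbg(map_r)))
})

test_that("LBG steepness ranks cold, temperate and hot climates", {
  g <- grid_spec(36, 36)
  strip <- list(continent(c(-80, 80), c(-10, 10)))
  pool <- generate_niche_pool(niche_params(n = 1500, seed = 10))
  steep <- function(eq, po) {
    w <- make_world(world_config(equator_sst = eq, pole_sst = po,
                                 seasonal_amplitude = 4,
                                 continents = strip), g)
    m <- shelf_mask(w)
    lbg_steepness(lbg(richness_map(pool, w, m)))
  }
  s_cold <- steep(18, -2)
  s_ref <- steep(28, -2)
  s_hot <- steep(40, 10)
  expect_gt(s_cold, s_ref)    # cooling steepens the gradient
  expect_gt(s_ref, s_hot)     # strong warming flattens ...
  expect_lt(s_hot, 0)         # ... and inverts it
})

test_that("external fragmentation series are ingested and interpolated", {
  coarse_ages <- seq(540, 0, by = -20)
  frag <- synth_fragmentation_index(coarse_ages, seed = 12)
  expect_true(all(frag$values >= 0 & frag$values <= 1))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_age_series(frag, path)
  back <- read_age_series(path, "fragmentation index")
  expect_equal(back$values, frag$values)
  fine <- interpolate_to_ages(back, seq(540, 0, by = -5))
  expect_length(fine$values, 109)
  # knots reproduced exactly after resampling to the simulation resolution
  expect_equal(fine$values[match(coarse_ages, fine$ages)], frag$values,
               tolerance = 1e-12)
})
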