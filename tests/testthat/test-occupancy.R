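toy_setup <- function(n_lat = 6, n_lon = 6, n_niches = 5, land_p = 0.3) {
  w <- random_toy_world(n_lat, n_lon, land_p)
  list(world = w, mask = shelf_mask(w, 2), pool = random_toy_pool(n_niches))
}

test_that("months_suitable equals the naive triple-loop oracle exactly", {
  set.seed(101)
  for (rep in 1:25) {
    ts <- toy_setup(sample(4:8, 1), sample(5:9, 1), sample(1:8, 1))
    got <- months_suitable(ts$pool, ts$world, ts$mask)
    expect_identical(got, brute_months_suitable(ts$pool, ts$world, ts$mask))
  }
})

test_that("suitability counts are independent of the niche block size", {
  set.seed(202)
  ts <- toy_setup(8, 10, 40)
  ref <- months_suitable(ts$pool, ts$world, ts$mask, block_size = 1000L)
  for (bs in c(1L, 3L, 7L, 40L))
    expect_identical(months_suitable(ts$pool, ts$world, ts$mask,
                                     block_size = bs), ref)
})

test_that("limit niches behave as expected on constant worlds", {
  g <- grid_spec(8, 8)
  w <- make_world(world_config(equator_sst = 20, pole_sst = 20,
                               seasonal_amplitude = 0,
                               continents = list(continent(c(-20, 0),
                                                           c(0, 40)))), g)
  m <- shelf_mask(w)
  all_temp <- niches_from_draws(1, 0.5, niche_params())   # [3, 39] covers 20
  cold <- niches_from_draws(1, 1, niche_params())          # [24, 44]
  pool <- structure(list(params = niche_params(n = 2),
                         lower = c(all_temp$lower, cold$lower),
                         upper = c(all_temp$upper, cold$upper)),
                    class = "niche_pool")
  ms <- months_suitable(pool, w, m)
  expect_true(all(ms[1, ] == 12L))
  expect_true(all(ms[2, ] == 0L))
  rmap <- richness_map(pool, w, m)
  expect_true(all(rmap$values[m$cells] == 1))
  expect_true(all(rmap$values[!m$cells] == 0))
})

test_that("monthly-mean richness maps match the brute-force oracle", {
  set.seed(303)
  for (rep in 1:10) {
    ts <- toy_setup(6, 6, 10)
    got <- richness_map(ts$pool, ts$world, ts$mask, "monthly_mean")
    expect_equal(got$values,
                 brute_monthly_mean_richness(ts$pool, ts$world, ts$mask))
  }
})

test_that("the epsilon-month rule applies a >= threshold", {
  # hand-built: one marine cell suitable exactly 8 of 12 months
  g <- grid_spec(4, 4)
  lm <- matrix(FALSE, 4, 4); lm[2, 2] <- TRUE
  sst <- array(rep(c(rep(10, 8), rep(30, 4)), each = 16), c(4, 4, 12))
  for (m in 1:12) { l <- sst[, , m]; l[lm] <- NA; sst[, , m] <- l }
  bath <- matrix(100, 4, 4); bath[lm] <- NA
  w <- world_slice(g, 0, lm, bath, sst)
  mask <- shelf_mask(w, 1)
  pool <- structure(list(params = niche_params(n = 1),
                         lower = 8, upper = 12), class = "niche_pool")
  cube8 <- annual_occupancy(pool, w, mask, epsilon = 8)
  expect_true(all(cube8$occupancy))
  cube9 <- annual_occupancy(pool, w, mask, epsilon = 9)
  expect_false(any(cube9$occupancy))
  cube1 <- annual_occupancy(pool, w, mask, epsilon = 1)
  expect_identical(cube1$occupancy, cube8$months_suitable >= 1L)
  expect_error(annual_occupancy(pool, w, mask, epsilon = 0), "epsilon")
  expect_error(annual_occupancy(pool, w, mask, epsilon = 13), "epsilon")
})

test_that("occupancy shrinks monotonically as epsilon rises", {
  # note: the per-niche *patch sum* is deliberately not asserted monotone --
  # losing cells can split a connected range into two isolated patches
  set.seed(404)
  ts <- toy_setup(8, 8, 15)
  prev_occ <- NULL
  prev_wo <- Inf
  for (eps in 1:12) {
    cube <- annual_occupancy(ts$pool, ts$world, ts$mask, epsilon = eps)
    if (!is.null(prev_occ)) expect_true(all(cube$occupancy <= prev_occ))
    counts <- global_richness(ts$pool, ts$world, ts$mask, epsilon = eps)
    expect_lte(counts$without_speciation, prev_wo)
    expect_gte(counts$with_speciation, counts$without_speciation)
    prev_occ <- cube$occupancy
    prev_wo <- counts$without_speciation
  }
})

test_that("patch counting agrees with a flood fill, including the seam", {
  set.seed(505)
  for (rep in 1:60) {
    map <- matrix(runif(20 * 20) < 0.35, 20, 20)
    for (conn in c(4L, 8L)) {
      expect_identical(count_patches(map, conn),
                       flood_fill_patches(map, conn))
      expect_identical(count_patches(map, conn, wrap = FALSE),
                       flood_fill_patches(map, conn, wrap = FALSE))
    }
  }
  # explicit seam-crossing blob: one patch with wrap, two without
  m <- matrix(FALSE, 5, 9)
  m[2:3, 1] <- TRUE; m[2:3, 9] <- TRUE
  expect_identical(count_patches(m), 1L)
  expect_identical(count_patches(m, wrap = FALSE), 2L)
  expect_identical(count_patches(matrix(FALSE, 4, 4)), 0L)
})

test_that("no patches connect across the poles", {
  m <- matrix(FALSE, 6, 8)
  m[1, 3] <- TRUE; m[6, 3] <- TRUE
  expect_identical(count_patches(m), 2L)
})

test_that("global richness counts match per-niche flood fills", {
  set.seed(606)
  for (rep in 1:10) {
    ts <- toy_setup(8, 8, 8)
    counts <- global_richness(ts$pool, ts$world, ts$mask)
    cube <- annual_occupancy(ts$pool, ts$world, ts$mask)
    oracle <- integer(length(ts$pool$lower))
    for (i in seq_along(oracle)) {
      map <- matrix(FALSE, 8, 8)
      map[cube$cells[cube$occupancy[i, ]]] <- TRUE
      oracle[i] <- flood_fill_patches(map, 8)
    }
    expect_identical(counts$per_niche_patches, oracle)
    expect_identical(counts$with_speciation, sum(oracle))
    expect_identical(counts$without_speciation,
                     sum(rowSums(cube$occupancy) > 0))
  }
})

test_that("a single shelf ring gives one patch per occupying niche", {
  g <- grid_spec(24, 24)
  w <- make_world(world_config(equator_sst = 20, pole_sst = 20,
                               seasonal_amplitude = 0,
                               continents = list(continent(c(-10, 10),
                                                           c(0, 40)))), g)
  counts <- global_richness(generate_niche_pool(niche_params(n = 500,
                                                             seed = 4)),
                            w, shelf_mask(w))
  expect_identical(counts$with_speciation, counts$without_speciation)
})

test_that("mirrored two-continent worlds double dual-shelf patch counts", {
  g <- grid_spec(36, 36)
  cfg2 <- world_config(equator_sst = 26, pole_sst = -2,
                       seasonal_amplitude = 4, noise_sd = 0,
                       continents = list(continent(c(-55, -45), c(-30, 30)),
                                         continent(c(45, 55), c(-30, 30))))
  w <- make_world(cfg2, g)
  mask <- shelf_mask(w)
  pool <- generate_niche_pool(niche_params(n = 800, seed = 8))
  cube <- annual_occupancy(pool, w, mask)
  counts <- global_richness(pool, w, mask)
  south <- g$lat[((cube$cells - 1) %% g$n_lat) + 1] < 0
  occ_s <- rowSums(cube$occupancy[, south, drop = FALSE]) > 0
  occ_n <- rowSums(cube$occupancy[, !south, drop = FALSE]) > 0
  dual <- occ_s & occ_n
  expect_gt(sum(dual), 0)
  # flood-fill the southern shelf alone: mirrored geometry doubles it
  south_patches <- integer(length(pool$lower))
  for (i in which(dual)) {
    map <- matrix(FALSE, g$n_lat, g$n_lon)
    map[cube$cells[south][cube$occupancy[i, south]]] <- TRUE
    south_patches[i] <- flood_fill_patches(map, 8)
  }
  expect_identical(counts$per_niche_patches[dual], 2L * south_patches[dual])
  # single-shelf niches keep a single patch on a contiguous ring
  single <- xor(occ_s, occ_n)
  expect_true(all(counts$per_niche_patches[single] == 1L))
})

test_that("richness maps are invariant under niche order and rotation", {
  set.seed(707)
  ts <- toy_setup(8, 10, 12)
  perm <- sample(12)
  shuffled <- structure(list(params = ts$pool$params,
                             lower = ts$pool$lower[perm],
                             upper = ts$pool$upper[perm]),
                        class = "niche_pool")
  m1 <- richness_map(ts$pool, ts$world, ts$mask)
  m2 <- richness_map(shuffled, ts$world, ts$mask)
  expect_equal(m1$values, m2$values)
  wr <- rotate_world(ts$world, 4)
  mr <- richness_map(ts$pool, wr, shelf_mask(wr, 2))
  idx <- ((seq_len(10) - 1 - 4) %% 10) + 1
  expect_equal(mr$values, m1$values[, idx])
})

test_that("splitting a continent in two never decreases speciation counts", {
  g <- grid_spec(36, 36)
  mk <- function(conts) make_world(world_config(equator_sst = 26,
    pole_sst = -2, seasonal_amplitude = 4, continents = conts), g, 100)
  one <- mk(list(continent(c(-20, 20), c(-30, 30))))
  two <- mk(list(continent(c(-20, 20), c(-70, -40)),
                 continent(c(-20, 20), c(40, 70))))
  pool <- generate_niche_pool(niche_params(n = 1000, seed = 6))
  c1 <- global_richness(pool, one, shelf_mask(one))
  c2 <- global_richness(pool, two, shelf_mask(two))
  expect_gte(c2$with_speciation, c1$with_speciation)
})

test_that("grid mismatches are rejected", {
  ts <- toy_setup(6, 6, 3)
  other <- random_toy_world(8, 8)
  expect_error(months_suitable(ts$pool, other, ts$mask), "grid")
})
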