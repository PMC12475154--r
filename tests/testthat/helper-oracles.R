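# Independent brute-force oracles. Everything here is written as literally
# as possible (explicit loops, no shared code with the package internals) so
# that agreement is evidence, not tautology.

# -- naive per-(niche, cell, month) suitability count ------------------------
brute_months_suitable <- function(pool, world, mask) {
  cells <- which(mask$cells)
  out <- matrix(0L, length(pool$lower), length(cells))
  for (i in seq_along(pool$lower)) {
    for (j in seq_along(cells)) {
      cnt <- 0L
      for (m in 1:12) {
        t <- world$sst[, , m][cells[j]]
        if (!is.na(t) && pool$lower[i] <= t && t <= pool$upper[i])
          cnt <- cnt + 1L
      }
      out[i, j] <- cnt
    }
  }
  out
}

brute_monthly_mean_richness <- function(pool, world, mask) {
  cells <- which(mask$cells)
  vals <- numeric(length(cells))
  for (j in seq_along(cells)) {
    total <- 0L
    for (m in 1:12) {
      t <- world$sst[, , m][cells[j]]
      if (!is.na(t))
        total <- total + sum(pool$lower <= t & t <= pool$upper)
    }
    vals[j] <- total / 12
  }
  out <- matrix(0, nrow(mask$cells), ncol(mask$cells))
  out[cells] <- vals
  out
}

# -- stack-based flood fill with explicit longitude wrap ---------------------
flood_fill_patches <- function(map, connectivity = 8, wrap = TRUE) {
  n_lat <- nrow(map); n_lon <- ncol(map)
  seen <- matrix(FALSE, n_lat, n_lon)
  deltas <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  n_patches <- 0L
  for (la0 in seq_len(n_lat)) {
    for (lo0 in seq_len(n_lon)) {
      if (!map[la0, lo0] || seen[la0, lo0]) next
      n_patches <- n_patches + 1L
      stack <- list(c(la0, lo0))
      seen[la0, lo0] <- TRUE
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in deltas) {
          la <- cur[1] + d[1]
          lo <- cur[2] + d[2]
          if (la < 1 || la > n_lat) next
          if (lo < 1) { if (!wrap) next; lo <- n_lon }
          if (lo > n_lon) { if (!wrap) next; lo <- 1 }
          if (map[la, lo] && !seen[la, lo]) {
            seen[la, lo] <- TRUE
            stack[[length(stack) + 1L]] <- c(la, lo)
          }
        }
      }
    }
  }
  n_patches
}

# -- exact niche-coverage probability by quadrature over d1 ------------------
# P(lower <= t <= upper) for the corrected breadth formula: condition on X,
# the centre Y is uniform on [alpha + X/2, beta - X/2].
coverage_integral <- function(t, alpha = -2, beta = 44, gamma = 4,
                              delta = 20) {
  f <- function(d1) {
    X <- d1 * (delta - gamma) + gamma
    lo <- pmax(t - X / 2, alpha + X / 2)
    hi <- pmin(t + X / 2, beta - X / 2)
    pmax(hi - lo, 0) / (beta - alpha - X)
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

# -- shape-preserving cubic interpolation oracle -----------------------------
# Published derivative rule: weighted harmonic mean of adjacent secant
# slopes where their signs agree (zero otherwise), one-sided cubic-fit end
# slopes limited to preserve shape; evaluated via the cubic Hermite basis.
pchip_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  del <- diff(y) / h
  d <- numeric(n)
  if (n > 2) {
    for (k in 2:(n - 1)) {
      if (sign(del[k - 1]) * sign(del[k]) > 0) {
        w1 <- 2 * h[k] + h[k - 1]
        w2 <- h[k] + 2 * h[k - 1]
        d[k] <- (w1 + w2) / (w1 / del[k - 1] + w2 / del[k])
      } else {
        d[k] <- 0
      }
    }
  }
  end_slope <- function(h1, h2, del1, del2) {
    dd <- ((2 * h1 + h2) * del1 - h1 * del2) / (h1 + h2)
    if (sign(dd) != sign(del1)) dd <- 0
    else if (sign(del1) != sign(del2) && abs(dd) > 3 * abs(del1))
      dd <- 3 * del1
    dd
  }
  d[1] <- end_slope(h[1], h[2], del[1], del[2])
  d[n] <- end_slope(h[n - 1], h[n - 2], del[n - 1], del[n - 2])
  vapply(xout, function(xx) {
    k <- max(1, min(n - 1, findInterval(xx, x, rightmost.closed = TRUE)))
    s <- (xx - x[k]) / h[k]
    h00 <- 2 * s^3 - 3 * s^2 + 1
    h10 <- s^3 - 2 * s^2 + s
    h01 <- -2 * s^3 + 3 * s^2
    h11 <- s^3 - s^2
    h00 * y[k] + h10 * h[k] * d[k] + h01 * y[k + 1] + h11 * h[k] * d[k + 1]
  }, numeric(1))
}

# -- standardised-PCA oracle: eigendecomposition of the correlation matrix --
pca_oracle <- function(mat) {
  z <- scale(mat, center = TRUE, scale = TRUE)
  eg <- eigen(stats::cor(mat), symmetric = TRUE)
  list(explained = eg$values / sum(eg$values),
       pc1_scores = as.numeric(z %*% eg$vectors[, 1]))
}

# -- toy-instance generator --------------------------------------------------
# Random small worlds built through the plain constructor: arbitrary land
# patterns (not just rectangles), random per-cell-month SSTs, random
# bathymetry. Guarantees at least one marine and at least one land cell.
random_toy_world <- function(n_lat, n_lon, land_p = 0.3, sst_range = c(-2, 32)) {
  grid <- grid_spec(n_lat, n_lon)
  repeat {
    landmask <- matrix(stats::runif(n_lat * n_lon) < land_p, n_lat, n_lon)
    if (any(landmask) && !all(landmask)) break
  }
  sst <- array(stats::runif(n_lat * n_lon * 12, sst_range[1], sst_range[2]),
               c(n_lat, n_lon, 12))
  for (m in 1:12) {
    layer <- sst[, , m]
    layer[landmask] <- NA_real_
    sst[, , m] <- layer
  }
  bathymetry <- matrix(stats::runif(n_lat * n_lon, 0, 2000), n_lat, n_lon)
  bathymetry[landmask] <- NA_real_
  world_slice(grid, age = 0, landmask, bathymetry, sst)
}

random_toy_pool <- function(n, alpha = -2, beta = 32) {
  lower <- stats::runif(n, alpha, beta - 1)
  upper <- lower + stats::runif(n, 0.5, beta - lower)
  structure(list(params = niche_params(alpha = alpha, beta = max(beta, 44),
                                       n = n),
                 lower = lower, upper = pmin(upper, beta)),
            class = "niche_pool")
}

# longitude rotation of a world slice (for equivariance properties)
rotate_world <- function(world, k) {
  idx <- ((seq_len(world$grid$n_lon) - 1 - k) %% world$grid$n_lon) + 1
  sst <- world$sst[, idx, , drop = FALSE]
  world_slice(world$grid, world$age, world$landmask[, idx, drop = FALSE],
              world$bathymetry[, idx, drop = FALSE], sst)
}
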