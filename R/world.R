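#' Rectangular continent definition
#'
#' Continents are lat-lon rectangles given by their edges in degrees.
#' A longitude pair with `lon[1] > lon[2]` wraps across the dateline.
#'
#' @param lat Length-2 numeric, southern and northern edge (degrees).
#' @param lon Length-2 numeric, western and eastern edge (degrees).
#' @return A list of class `continent`.
#' @export
continent <- function(lat, lon) {
  stopifnot(length(lat) == 2, length(lon) == 2, lat[1] <= lat[2],
            lat[1] >= -90, lat[2] <= 90)
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon)),
            class = "continent")
}

#' Configuration of a synthetic palaeo-world
#'
#' Describes the idealised climate and palaeogeography from which
#' [make_world()] builds a time slice. The monthly sea-surface temperature
#' at latitude phi and month m is
#' `pole_sst + (equator_sst - pole_sst) * cos(phi)^2 +
#'  seasonal_amplitude * sin(phi) * cos(2*pi*(m - 7)/12) + noise`,
#' i.e. a smooth poleward gradient plus a hemispherically anti-phased
#' seasonal cycle (Northern-Hemisphere maximum in July, zero at the
#' equator), clipped below at -2 degC (freezing sea water). Inverted
#' gradients (`equator_sst < pole_sst`) are admissible for warm-world
#' experiments. Bathymetry grows linearly with grid distance from land
#' (`shelf_slope` metres per cell), capped at `abyssal_depth`.
#'
#' @param equator_sst Annual-mean SST at the equator, degC.
#' @param pole_sst Annual-mean SST at the poles, degC.
#' @param seasonal_amplitude Peak seasonal half-range at the poles, degC.
#' @param continents List of [continent()] rectangles (possibly empty).
#' @param shelf_slope Depth increase per cell away from land, metres.
#' @param abyssal_depth Maximum (open-ocean) depth, metres.
#' @param noise_sd Standard deviation of cell/month Gaussian noise, degC.
#' @param seed Integer seed; each slice derives its own RNG stream from
#'   `(seed, age)` so slices are independent and order-insensitive.
#' @return A list of class `world_config`.
#' @export
world_config <- function(equator_sst = 28, pole_sst = -2,
                         seasonal_amplitude = 8, continents = list(),
                         shelf_slope = 400, abyssal_depth = 4500,
                         noise_sd = 0, seed = 1L) {
  stopifnot(is.numeric(equator_sst), is.numeric(pole_sst),
            seasonal_amplitude >= 0, shelf_slope >= 0, abyssal_depth > 0,
            noise_sd >= 0)
  if (inherits(continents, "continent")) continents <- list(continents)
  stopifnot(all(vapply(continents, inherits, logical(1), "continent")))
  structure(
    list(equator_sst = equator_sst, pole_sst = pole_sst,
         seasonal_amplitude = seasonal_amplitude, continents = continents,
         shelf_slope = shelf_slope, abyssal_depth = abyssal_depth,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "world_config"
  )
}

#' Construct a world slice from its components
#'
#' Low-level constructor validating the invariants shared by synthetic and
#' ingested palaeoclimate slices: SST defined exactly on marine cells for
#' all 12 months and nowhere below -2 degC; bathymetry non-negative on
#' marine cells and undefined (NA) on land.
#'
#' @param grid A [grid_spec()].
#' @param age Age of the slice in Ma (>= 0).
#' @param landmask Logical `[n_lat, n_lon]` matrix, `TRUE` = emerged land.
#' @param bathymetry Numeric `[n_lat, n_lon]` matrix, metres below sea
#'   level on marine cells, `NA` on land.
#' @param sst Numeric `[n_lat, n_lon, 12]` array, degC, `NA` on land.
#' @return An object of class `world_slice`.
#' @export
world_slice <- function(grid, age, landmask, bathymetry, sst) {
  stopifnot(inherits(grid, "grid_spec"), is.numeric(age), age >= 0)
  dm <- c(grid$n_lat, grid$n_lon)
  stopifnot(is.logical(landmask), all(dim(landmask) == dm))
  stopifnot(is.numeric(bathymetry), all(dim(bathymetry) == dm))
  if (length(dim(sst)) != 3 || !all(dim(sst) == c(dm, 12L)))
    stop("sst must be an [n_lat, n_lon, 12] array (12 monthly layers)")
  marine <- !landmask
  for (m in 1:12) {
    layer <- sst[, , m]
    if (anyNA(layer[marine]))
      stop("sst must be defined on every marine cell in every month")
    if (any(!is.na(layer[landmask])))
      stop("sst must be undefined (NA) on land cells")
  }
  if (min(sst, na.rm = TRUE) < -2 - 1e-9)
    stop("sst below -2 degC (sea water would be frozen)")
  if (any(is.na(bathymetry[marine])) || any(bathymetry[marine] < 0))
    stop("bathymetry must be >= 0 on all marine cells")
  if (any(!is.na(bathymetry[landmask])))
    stop("bathymetry must be undefined (NA) on land cells")
  structure(list(grid = grid, age = as.numeric(age), landmask = landmask,
                 bathymetry = bathymetry, sst = sst),
            class = "world_slice")
}

#' @export
print.world_slice <- function(x, ...) {
  cat(sprintf(
    "<world_slice> age %.1f Ma, %d x %d grid, %d land / %d marine cells\n",
    x$age, x$grid$n_lat, x$grid$n_lon, sum(x$landmask), sum(!x$landmask)))
  invisible(x)
}

# Deterministic per-slice seed derived from (seed, age); kept below 2^31.
slice_seed <- function(seed, age) {
  as.integer((as.double(seed) * 7919 + round(age * 131)) %% 2147483629)
}

# Evaluate an expression with a local RNG stream, restoring global state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

continent_mask <- function(grid, continents) {
  mask <- matrix(FALSE, grid$n_lat, grid$n_lon)
  lon <- ((grid$lon + 180) %% 360) - 180
  for (ct in continents) {
    in_lat <- grid$lat >= ct$lat[1] & grid$lat <= ct$lat[2]
    if (ct$lon[2] - ct$lon[1] >= 360) {
      in_lon <- rep(TRUE, grid$n_lon)
    } else {
      l1 <- ((ct$lon[1] + 180) %% 360) - 180
      l2 <- ((ct$lon[2] + 180) %% 360) - 180
      in_lon <- if (l1 <= l2) lon >= l1 & lon <= l2
                else lon >= l1 | lon <= l2
    }
    mask[in_lat, in_lon] <- TRUE
  }
  mask
}

#' Generate one synthetic world slice
#'
#' Builds a [world_slice()] whose monthly SST field follows the idealised
#' climate in [world_config()]: annual mean `pole + (equator - pole) *
#' cos(phi)^2`, an anti-phased seasonal cycle `amplitude * sin(phi) *
#' cos(2*pi*(m - 7)/12)` (July maximum in the Northern Hemisphere, reversed
#' in the south, zero at the equator), optional Gaussian noise, and a floor
#' at -2 degC. Bathymetry is `shelf_slope` times the grid (Chebyshev)
#' distance to the nearest land cell, capped at `abyssal_depth`; with no
#' land, the whole ocean sits at `abyssal_depth`.
#'
#' @param config A [world_config()].
#' @param grid A [grid_spec()].
#' @param age Age in Ma.
#' @return A [world_slice()].
#' @examples
#' w <- make_world(world_config(continents = continent(c(-30, 10), c(0, 60))),
#'                 grid_spec(36, 36), age = 250)
#' @export
make_world <- function(config, grid, age = 0) {
  stopifnot(inherits(config, "world_config"), inherits(grid, "grid_spec"))
  landmask <- continent_mask(grid, config$continents)
  if (all(landmask)) stop("no marine cells: continents cover the whole grid")

  phi <- grid$lat * pi / 180
  annual <- config$pole_sst +
    (config$equator_sst - config$pole_sst) * cos(phi)^2
  months <- 1:12
  seasonal <- outer(sin(phi), cos(2 * pi * (months - 7) / 12)) *
    config$seasonal_amplitude                       # [n_lat, 12]

  sst <- array(NA_real_, c(grid$n_lat, grid$n_lon, 12L))
  noise <- if (config$noise_sd > 0) {
    with_local_seed(slice_seed(config$seed, age),
                    array(stats::rnorm(grid$n_lat * grid$n_lon * 12L,
                                       sd = config$noise_sd),
                          c(grid$n_lat, grid$n_lon, 12L)))
  } else 0
  for (m in months) {
    layer <- matrix(annual + seasonal[, m], grid$n_lat, grid$n_lon)
    if (config$noise_sd > 0) layer <- layer + noise[, , m]
    layer <- pmax(layer, -2)
    layer[landmask] <- NA_real_
    sst[, , m] <- layer
  }

  dist <- grid_distance(landmask, "chebyshev")
  bathymetry <- pmin(config$shelf_slope * dist, config$abyssal_depth)
  bathymetry[landmask] <- NA_real_

  world_slice(grid, age, landmask, bathymetry, sst)
}

interp_num <- function(a, b, f) a + f * (b - a)

interp_config <- function(c_old, c_young, f) {
  conts_old <- c_old$continents
  conts_young <- c_young$continents
  conts <- if (length(conts_old) == length(conts_young)) {
    # matched counts: interpolate each rectangle's edges
    Map(function(a, b) continent(interp_num(a$lat, b$lat, f),
                                 interp_num(a$lon, b$lon, f)),
        conts_old, conts_young)
  } else if (f < 1) conts_old else conts_young   # fragmentation: step change
  world_config(
    equator_sst = interp_num(c_old$equator_sst, c_young$equator_sst, f),
    pole_sst = interp_num(c_old$pole_sst, c_young$pole_sst, f),
    seasonal_amplitude = interp_num(c_old$seasonal_amplitude,
                                    c_young$seasonal_amplitude, f),
    continents = conts,
    shelf_slope = interp_num(c_old$shelf_slope, c_young$shelf_slope, f),
    abyssal_depth = interp_num(c_old$abyssal_depth, c_young$abyssal_depth, f),
    noise_sd = interp_num(c_old$noise_sd, c_young$noise_sd, f),
    seed = c_old$seed
  )
}

#' Generate a multi-slice continental-drift scenario
#'
#' Interpolates between configuration waypoints to produce one
#' [world_slice()] per requested age (old to young). When consecutive
#' waypoints hold the same number of continents, each rectangle's edges are
#' interpolated linearly in age (as are the scalar climate parameters);
#' when the counts differ (a fragmentation waypoint, e.g. one block
#' splitting into several), the older configuration holds until the younger
#' waypoint's age is reached.
#'
#' @param waypoints List of `list(age =, config =)` entries, ages strictly
#'   decreasing (old to young), configs from [world_config()].
#' @param grid A [grid_spec()].
#' @param ages Numeric vector of target ages, strictly decreasing, within
#'   the waypoint age span.
#' @return A list of [world_slice()] objects, one per age.
#' @export
make_drift_scenario <- function(waypoints, grid, ages) {
  stopifnot(length(waypoints) >= 1, inherits(grid, "grid_spec"))
  wp_ages <- vapply(waypoints, function(w) as.numeric(w$age), numeric(1))
  if (length(wp_ages) > 1 && any(diff(wp_ages) >= 0))
    stop("waypoint ages must be strictly decreasing (old to young)")
  if (any(diff(ages) >= 0))
    stop("target ages must be strictly decreasing (old to young)")
  if (max(ages) > max(wp_ages) || min(ages) < min(wp_ages))
    stop("target ages outside the waypoint age span")
  lapply(ages, function(a) {
    if (length(waypoints) == 1L)
      return(make_world(waypoints[[1L]]$config, grid, a))
    i <- max(which(wp_ages >= a - 1e-9))
    if (i == length(waypoints)) i <- i - 1L
    f <- (wp_ages[i] - a) / (wp_ages[i] - wp_ages[i + 1L])
    f <- min(max(f, 0), 1)
    make_world(interp_config(waypoints[[i]]$config,
                             waypoints[[i + 1L]]$config, f), grid, a)
  })
}
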