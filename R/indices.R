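#' Latitudinal biodiversity gradient (LBG) of a richness map
#'
#' Mean species richness per latitude row, averaged over the masked marine
#' cells of that row. Rows with no masked cells are flagged `NA` (they are
#' excluded from profiles, not zero-filled).
#'
#' @param map A [richness_map()].
#' @return A data.frame of class `lat_profile` with columns `lat`, `value`
#'   and `n_cells` (masked cells per row).
#' @export
lbg <- function(map) {
  stopifnot(inherits(map, "richness_map"))
  n_row <- rowSums(map$mask$cells)
  total <- rowSums(map$values * map$mask$cells)
  value <- ifelse(n_row > 0, total / pmax(n_row, 1L), NA_real_)
  structure(data.frame(lat = map$grid$lat, value = value, n_cells = n_row),
            class = c("lat_profile", "data.frame"))
}

# Occupied (>= 1 species) shelf cells per latitude row, under the annual
# epsilon-qualified definition; the "sum" reading instead accumulates the
# occupied-cell count of each of the 12 months.
occupied_by_lat <- function(cube, months = c("annual", "sum")) {
  months <- match.arg(months)
  n_lat <- cube$grid$n_lat
  la <- ((cube$cells - 1L) %% n_lat) + 1L
  if (months == "annual") {
    occ_cell <- colSums(cube$occupancy) > 0
    counts <- tabulate(la[occ_cell], nbins = n_lat)
  } else {
    counts <- integer(n_lat)
    for (m in 1:12)
      counts <- counts + tabulate(la[cube$monthly_presence[, m]],
                                  nbins = n_lat)
  }
  as.integer(counts)
}

#' Latitudinal continental index (LCI)
#'
#' The count of shelf cells holding at least one species, accumulated over
#' all latitudes. The default reading (`months = "annual"`) counts cells
#' occupied under the annual epsilon-month rule; `months = "sum"` instead
#' sums the monthly occupied-cell counts over the 12 months (cell-months),
#' an alternative reading of "for all months" that is exposed but not
#' asserted as the original one.
#'
#' @param cube An [annual_occupancy()] cube.
#' @param months `"annual"` (default) or `"sum"`.
#' @return Scalar count (cells, or cell-months for `"sum"`).
#' @export
lci <- function(cube, months = c("annual", "sum")) {
  stopifnot(inherits(cube, "occupancy_cube"))
  as.integer(sum(occupied_by_lat(cube, match.arg(months))))
}

#' LBG-weighted latitudinal continental index
#'
#' Multiplies the occupied shelf-cell count of each latitude by the
#' latitudinal mean species richness (the LBG value) and sums over
#' latitudes, capturing the joint influence of landmass location and the
#' gradient. Latitudes with no masked cells contribute 0.
#'
#' @param cube An [annual_occupancy()] cube.
#' @param lbg_profile A [lbg()] profile on the same latitude axis
#'   (conventionally from the monthly-mean richness map of the same slice).
#' @param months Occupied-cell reading, as in [lci()].
#' @return Scalar index.
#' @export
lbg_weighted_lci <- function(cube, lbg_profile,
                             months = c("annual", "sum")) {
  stopifnot(inherits(cube, "occupancy_cube"),
            inherits(lbg_profile, "lat_profile"))
  if (nrow(lbg_profile) != cube$grid$n_lat ||
      max(abs(lbg_profile$lat - cube$grid$lat)) > 1e-9)
    stop("LBG profile is not on the world's latitude axis")
  counts <- occupied_by_lat(cube, match.arg(months))
  w <- lbg_profile$value
  w[is.na(w)] <- 0
  sum(counts * w)
}

#' Temperature-density diagnostics of a slice
#'
#' Tallies the (cell, month) SST samples of the shelf mask into 1-degC
#' bins (default -2 to 41 degC), and reports the modal bin (temperature
#' interval holding the maximum number of observations) and the mean SST.
#' Samples outside the bin range are counted into the extreme bins so no
#' observation is lost.
#'
#' @param world A [world_slice()].
#' @param mask A [shelf_mask()] on the same grid.
#' @param bin_min,bin_max,bin_width Bin specification in degC.
#' @return A list of class `temperature_density`: `breaks`, `counts`,
#'   `modal_bin` (lower edge of the modal interval; NA when empty),
#'   `mean_sst`, `n`.
#' @export
temperature_density <- function(world, mask, bin_min = -2, bin_max = 41,
                                bin_width = 1) {
  stopifnot(inherits(world, "world_slice"), inherits(mask, "shelf_mask"))
  check_same_grid(world, mask)
  tm <- mask_sst(world, mask)
  x <- tm[is.finite(tm)]
  breaks <- seq(bin_min, bin_max, by = bin_width)
  if (length(x) == 0) {
    return(structure(list(breaks = breaks,
                          counts = integer(length(breaks) - 1L),
                          modal_bin = NA_real_, mean_sst = NA_real_, n = 0L),
                     class = "temperature_density"))
  }
  xc <- pmin(pmax(x, bin_min), bin_max - bin_width / 1e6)
  counts <- as.integer(table(cut(xc, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  structure(list(breaks = breaks, counts = counts,
                 modal_bin = breaks[which.max(counts)],
                 mean_sst = mean(x), n = length(x)),
            class = "temperature_density")
}

#' Steepness of a latitudinal biodiversity gradient
#'
#' A scalar summary used to compare LBG shapes across climates: the mean
#' profile value in the low-latitude band minus the mean in the
#' high-latitude band (rows without shelf cells excluded). Positive values
#' indicate the familiar equatorward increase; values near zero a flat
#' gradient; negative values an inverted gradient.
#'
#' @param profile A [lbg()] profile.
#' @param low_band Absolute-latitude ceiling of the "equatorial" band.
#' @param high_band Absolute-latitude floor of the "polar" band.
#' @return Scalar steepness (species per cell).
#' @export
lbg_steepness <- function(profile, low_band = 15, high_band = 45) {
  stopifnot(inherits(profile, "lat_profile"))
  ok <- !is.na(profile$value)
  low <- ok & abs(profile$lat) <= low_band
  high <- ok & abs(profile$lat) >= high_band
  if (!any(low) || !any(high))
    stop("no shelf latitudes in one of the comparison bands")
  mean(profile$value[low]) - mean(profile$value[high])
}
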