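#' The eight shelf ("around continents") mask variants
#'
#' Marine areas around continents are characterised by a ring width of 1 or
#' 2 grid cells around land, optionally intersected with a bathymetry
#' ceiling of <600, <1000 or <1500 m below sea level -- eight admissible
#' combinations in all. The main characterisation used throughout the
#' package defaults is the 2-cell ring with no depth limit.
#'
#' @return A data.frame with columns `ring_width` (1 or 2) and
#'   `depth_limit` (metres; `Inf` = no limit), 8 rows.
#' @examples
#' nrow(shelf_variants())   # 8
#' @export
shelf_variants <- function() {
  v <- expand.grid(ring_width = c(1L, 2L),
                   depth_limit = c(Inf, 600, 1000, 1500))
  v <- v[order(v$ring_width, v$depth_limit), c("ring_width", "depth_limit")]
  rownames(v) <- NULL
  v
}

#' Marine cells around continents (shelf mask)
#'
#' A marine cell belongs to the mask iff its grid distance (in cells, with
#' longitude wrap, no polar wrap) to the nearest land cell is at most
#' `ring_width`, and -- when a depth limit is given -- its bathymetry is
#' strictly shallower than `depth_limit` metres. Adjacency defaults to
#' 8-neighbour (Chebyshev distance), so diagonal coastal cells count as
#' adjacent; 4-neighbour (Manhattan) is available via `adjacency`.
#'
#' @param world A [world_slice()].
#' @param ring_width 1 or 2 cells around land.
#' @param depth_limit Depth ceiling in metres (strict `<`); `Inf` for none.
#' @param adjacency `"chebyshev"` (default) or `"manhattan"`.
#' @return An object of class `shelf_mask`: logical `cells` matrix
#'   (`TRUE` only on marine cells), the grid and the variant fields.
#' @examples
#' w <- make_world(world_config(continents = continent(c(-10, 10), c(0, 40))),
#'                 grid_spec(24, 24))
#' sum(shelf_mask(w, ring_width = 1)$cells)
#' @export
shelf_mask <- function(world, ring_width = 2L, depth_limit = Inf,
                       adjacency = c("chebyshev", "manhattan")) {
  stopifnot(inherits(world, "world_slice"))
  adjacency <- match.arg(adjacency)
  if (!ring_width %in% c(1L, 2L)) stop("ring_width must be 1 or 2")
  stopifnot(depth_limit > 0)
  if (all(world$landmask)) stop("no marine cells")
  if (!any(world$landmask)) {
    warning("world has no land cells; shelf mask is empty")
    cells <- matrix(FALSE, world$grid$n_lat, world$grid$n_lon)
  } else {
    d <- grid_distance(world$landmask, adjacency)
    cells <- !world$landmask & d <= ring_width
    if (is.finite(depth_limit))
      cells <- cells & !is.na(world$bathymetry) &
        world$bathymetry < depth_limit
  }
  structure(list(cells = cells, grid = world$grid,
                 ring_width = as.integer(ring_width),
                 depth_limit = depth_limit, adjacency = adjacency),
            class = "shelf_mask")
}

#' @export
print.shelf_mask <- function(x, ...) {
  lim <- if (is.finite(x$depth_limit)) sprintf("<%g m", x$depth_limit)
         else "no depth limit"
  cat(sprintf("<shelf_mask> ring %d (%s), %s: %d cells\n",
              x$ring_width, x$adjacency, lim, sum(x$cells)))
  invisible(x)
}

#' Total surface area of a shelf mask
#'
#' Sums WGS-84 cell areas over the masked cells, giving the available
#' marine area around continents for a time slice, in km^2.
#'
#' @param mask A [shelf_mask()].
#' @param areas Optional `[n_lat, n_lon]` area matrix (km^2), e.g. from
#'   [cell_areas()]; computed from the mask's grid when omitted.
#' @return Scalar area in km^2.
#' @export
shelf_area <- function(mask, areas = NULL) {
  stopifnot(inherits(mask, "shelf_mask"))
  if (is.null(areas)) areas <- cell_areas(mask$grid)
  stopifnot(all(dim(areas) == dim(mask$cells)))
  sum(areas[mask$cells])
}
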