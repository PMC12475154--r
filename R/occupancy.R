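# Core projection engine: niches x shelf cells x months. Everything here is
# computed in niche blocks so memory stays bounded; results are independent
# of the block size.

# SSTs of the masked cells as an [n_cells, 12] matrix (NA months possible in
# ingested fields; NA counts as unsuitable).
mask_sst <- function(world, mask) {
  cells <- which(mask$cells)
  out <- matrix(NA_real_, length(cells), 12L)
  for (m in 1:12) out[, m] <- world$sst[, , m][cells]
  out
}

check_same_grid <- function(world, mask, pool = NULL) {
  if (!identical(unclass(world$grid)[c("n_lat", "n_lon")],
                 unclass(mask$grid)[c("n_lat", "n_lon")]))
    stop("world and mask are not on the same grid")
  invisible(TRUE)
}

# Walk the pool in blocks; f(idx, suit_by_month) is called per block with
# suit_by_month a list of 12 logical [block, n_cells] matrices.
project_blocks <- function(pool, tm, block_size, f) {
  n <- length(pool$lower)
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, n)
    lo <- pool$lower[idx]
    up <- pool$upper[idx]
    suit <- vector("list", 12L)
    for (m in 1:12) {
      t_m <- tm[, m]
      sm <- outer(lo, t_m, "<=") & outer(up, t_m, ">=")
      sm[, is.na(t_m)] <- FALSE
      suit[[m]] <- sm
    }
    f(idx, suit)
  }
  invisible(NULL)
}

#' Number of thermally suitable months per niche and shelf cell
#'
#' For every niche and masked cell, counts the months m in 1..12 whose SST
#' lies inside the niche interval (closed bounds). Cells with missing SST
#' in a month count that month as unsuitable.
#'
#' @param pool A `niche_pool`.
#' @param world A [world_slice()].
#' @param mask A [shelf_mask()] on the same grid.
#' @param block_size Niches processed per block (memory knob only; the
#'   result is independent of it).
#' @return Integer matrix `[n_niches, n_mask_cells]`; the cell order is
#'   `which(mask$cells)` (column-major grid order).
#' @export
months_suitable <- function(pool, world, mask, block_size = 2000L) {
  stopifnot(inherits(pool, "niche_pool"), inherits(world, "world_slice"),
            inherits(mask, "shelf_mask"))
  check_same_grid(world, mask)
  tm <- mask_sst(world, mask)
  out <- matrix(0L, length(pool$lower), nrow(tm))
  project_blocks(pool, tm, block_size, function(idx, suit) {
    acc <- matrix(0L, length(idx), nrow(tm))
    for (m in 1:12) acc <- acc + suit[[m]]
    out[idx, ] <<- acc
  })
  out
}

#' Annual occupancy of every niche under the epsilon-month rule
#'
#' A niche maintains annually in a shelf cell iff at least `epsilon` of the
#' 12 months are thermally suitable there (default epsilon = 8). The
#' resulting boolean cube is the basis of the global species counts and of
#' allopatric-speciation patch counting.
#'
#' @inheritParams months_suitable
#' @param epsilon Minimum number of suitable months, in 1..12.
#' @return An object of class `occupancy_cube` with fields
#'   `months_suitable` (integer `[n_niches, n_cells]`), `occupancy`
#'   (logical, same shape), `cells` (grid indices of mask cells),
#'   `monthly_presence` (logical `[n_cells, 12]`: any niche suitable that
#'   month), `epsilon`, `grid`, `mask`.
#' @export
annual_occupancy <- function(pool, world, mask, epsilon = 8L,
                             block_size = 2000L) {
  if (!(epsilon >= 1 && epsilon <= 12)) stop("epsilon must be in 1..12")
  ms <- months_suitable(pool, world, mask, block_size)
  tm <- mask_sst(world, mask)
  monthly_presence <- matrix(FALSE, nrow(tm), 12L)
  # presence per (cell, month): any niche suitable; recomputed blockwise to
  # avoid a niches x cells x months cube
  project_blocks(pool, tm, block_size, function(idx, suit) {
    for (m in 1:12)
      monthly_presence[, m] <<- monthly_presence[, m] | colSums(suit[[m]]) > 0
  })
  structure(list(months_suitable = ms, occupancy = ms >= epsilon,
                 cells = which(mask$cells),
                 monthly_presence = monthly_presence,
                 epsilon = as.integer(epsilon), grid = world$grid,
                 mask = mask),
            class = "occupancy_cube")
}

#' Species richness map of a world slice
#'
#' `mode = "monthly_mean"` (the mapping definition): per cell, the count of
#' suitable niches is formed month by month, the 12 monthly richness maps
#' are summed and averaged, giving a real-valued map. `mode = "annual"`:
#' per cell, the count of niches with at least `epsilon` suitable months.
#' Richness is 0 outside the shelf mask.
#'
#' @inheritParams months_suitable
#' @param mode `"monthly_mean"` (default) or `"annual"`.
#' @param epsilon Month threshold used by the `"annual"` mode.
#' @return An object of class `richness_map`: numeric `values` matrix
#'   `[n_lat, n_lon]`, plus `grid`, `mask` and `mode`.
#' @export
richness_map <- function(pool, world, mask,
                         mode = c("monthly_mean", "annual"), epsilon = 8L,
                         block_size = 2000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(pool, "niche_pool"), inherits(world, "world_slice"),
            inherits(mask, "shelf_mask"))
  check_same_grid(world, mask)
  tm <- mask_sst(world, mask)
  vals <- numeric(nrow(tm))
  if (mode == "monthly_mean") {
    project_blocks(pool, tm, block_size, function(idx, suit) {
      for (m in 1:12) vals <<- vals + colSums(suit[[m]])
    })
    vals <- vals / 12
  } else {
    if (!(epsilon >= 1 && epsilon <= 12)) stop("epsilon must be in 1..12")
    project_blocks(pool, tm, block_size, function(idx, suit) {
      acc <- matrix(0L, length(idx), nrow(tm))
      for (m in 1:12) acc <- acc + suit[[m]]
      vals <<- vals + colSums(acc >= epsilon)
    })
  }
  values <- matrix(0, world$grid$n_lat, world$grid$n_lon)
  values[which(mask$cells)] <- vals
  structure(list(values = values, grid = world$grid, mask = mask,
                 mode = mode),
            class = "richness_map")
}

#' @export
print.richness_map <- function(x, ...) {
  cat(sprintf("<richness_map> %s, max %.2f species/cell on %d shelf cells\n",
              x$mode, max(x$values), sum(x$mask$cells)))
  invisible(x)
}

# --- connected components on the periodic grid -----------------------------

# Neighbour pairs among TRUE cells of `map` (grid indices, column-major),
# one row per undirected edge; longitude wraps, poles do not.
patch_edges <- function(map, connectivity = 8L, wrap = TRUE) {
  dirs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) dirs <- c(dirs, list(c(1L, 1L), c(1L, -1L)))
  n_lat <- nrow(map)
  pairs <- list()
  for (d in dirs) {
    shifted <- shift_grid(map, d[1L], d[2L], wrap = wrap)
    both <- map & shifted
    ids <- which(both)
    if (!length(ids)) next
    la <- ((ids - 1L) %% n_lat) + 1L
    lo <- ((ids - 1L) %/% n_lat) + 1L
    la2 <- la - d[1L]
    lo2 <- ((lo - d[2L] - 1L) %% ncol(map)) + 1L
    pairs[[length(pairs) + 1L]] <- cbind(ids, (lo2 - 1L) * n_lat + la2)
  }
  if (!length(pairs)) return(matrix(integer(0), 0L, 2L))
  do.call(rbind, pairs)
}

# Union-find: number of merges performed over the given edges, vertices
# labelled 1..n_vertices.
uf_merge_count <- function(n_vertices, ei, ej) {
  parent <- seq_len(n_vertices)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]   # path halving
      x <- parent[x]
    }
    x
  }
  merges <- 0L
  for (k in seq_along(ei)) {
    a <- find_root(ei[k])
    b <- find_root(ej[k])
    if (a != b) {
      parent[a] <- b
      merges <- merges + 1L
    }
  }
  merges
}

#' Count isolated patches of a presence map
#'
#' Number of connected components of the TRUE cells of a boolean grid map,
#' under 8-neighbour (default) or 4-neighbour connectivity, with
#' longitude wrap-around and no connection across the poles. Under
#' allopatric speciation each isolated patch of a niche's annual occupancy
#' is one potential species; 8-connectivity keeps diagonally touching
#' coastal cells in one population, the conservative choice.
#'
#' @param map Logical `[n_lat, n_lon]` matrix.
#' @param connectivity 8 (default) or 4.
#' @param wrap Wrap the longitude axis (default TRUE).
#' @return Integer patch count; 0 for an all-FALSE map.
#' @examples
#' m <- matrix(FALSE, 5, 8); m[2, c(1, 8)] <- TRUE
#' count_patches(m)               # 1: the blob spans the longitude seam
#' count_patches(m, wrap = FALSE) # 2
#' @export
count_patches <- function(map, connectivity = 8L, wrap = TRUE) {
  stopifnot(is.logical(map), is.matrix(map))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  ids <- which(map)
  n <- length(ids)
  if (n == 0L) return(0L)
  edges <- patch_edges(map, connectivity, wrap)
  if (!nrow(edges)) return(n)
  ei <- match(edges[, 1L], ids)
  ej <- match(edges[, 2L], ids)
  n - uf_merge_count(n, ei, ej)
}

# Patch counts for many niches sharing one mask: adjacency among mask cells
# is precomputed once; per niche, only edges with both ends occupied are
# unioned. `occ` is logical [n_niches, n_cells]; returns integer vector.
patch_counts_on_mask <- function(occ, mask, connectivity = 8L) {
  cells <- which(mask$cells)
  edges <- patch_edges(mask$cells, connectivity, wrap = TRUE)
  ei <- match(edges[, 1L], cells)
  ej <- match(edges[, 2L], cells)
  n_cells <- length(cells)
  vapply(seq_len(nrow(occ)), function(i) {
    o <- occ[i, ]
    n_occ <- sum(o)
    if (n_occ == 0L) return(0L)
    keep <- o[ei] & o[ej]
    if (!any(keep)) return(n_occ)
    as.integer(n_occ - uf_merge_count(n_cells, ei[keep], ej[keep]))
  }, integer(1))
}

#' Global species richness of a slice, with and without speciation
#'
#' Without allopatric speciation one niche gives at most one species: the
#' count is the number of niches whose annual occupancy is non-empty. With
#' allopatric speciation each isolated occupancy patch is a potential
#' species, so the count is the sum of per-niche patch counts. Both are
#' always reported; `with_speciation >= without_speciation` by
#' construction.
#'
#' @inheritParams annual_occupancy
#' @param connectivity Patch connectivity, 8 (default) or 4.
#' @return An object of class `species_counts`: `without_speciation`,
#'   `with_speciation`, and `per_niche_patches` (integer vector).
#' @export
global_richness <- function(pool, world, mask, epsilon = 8L,
                            connectivity = 8L, block_size = 2000L) {
  cube <- annual_occupancy(pool, world, mask, epsilon, block_size)
  patches <- patch_counts_on_mask(cube$occupancy, mask, connectivity)
  structure(list(without_speciation = sum(rowSums(cube$occupancy) > 0),
                 with_speciation = sum(patches),
                 per_niche_patches = patches),
            class = "species_counts")
}

#' @export
print.species_counts <- function(x, ...) {
  cat(sprintf("<species_counts> %d without / %d with allopatric speciation\n",
              x$without_speciation, x$with_speciation))
  invisible(x)
}
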