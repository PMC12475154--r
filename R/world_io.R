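#' Write / read a world slice as self-describing text
#'
#' Serialises a [world_slice()] to a plain-text file: header lines
#' (`# key=value`) carrying the grid geometry and the `age_ma` attribute,
#' followed by one CSV row per cell with columns `lat_idx`, `lon_idx`,
#' `landmask`, `bathymetry`, `sst_01` .. `sst_12`. The same dialect is the
#' ingestion format for real palaeoclimate fields exported from gridded
#' (e.g. netCDF) sources. Round-trips are lossless for the landmask and
#' bathymetry and lossless to numeric printing precision for SST.
#' `read_world` accepts the landmask as logicals or 0/1 integers.
#'
#' @param world A [world_slice()].
#' @param path File path.
#' @return `write_world` returns `path` invisibly; `read_world` a
#'   [world_slice()].
#' @export
write_world <- function(world, path) {
  stopifnot(inherits(world, "world_slice"))
  g <- world$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# palaeoniche world_slice v1",
    sprintf("# age_ma=%.17g", world$age),
    sprintf("# n_lat=%d", g$n_lat),
    sprintf("# n_lon=%d", g$n_lon),
    sprintf("# lat=%s", paste(sprintf("%.17g", g$lat), collapse = ",")),
    sprintf("# lon=%s", paste(sprintf("%.17g", g$lon), collapse = ","))
  ), con)
  df <- data.frame(
    lat_idx = rep(seq_len(g$n_lat), times = g$n_lon),
    lon_idx = rep(seq_len(g$n_lon), each = g$n_lat),
    landmask = as.integer(world$landmask),
    bathymetry = as.vector(world$bathymetry)
  )
  for (m in 1:12) df[[sprintf("sst_%02d", m)]] <- as.vector(world$sst[, , m])
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_world
#' @export
read_world <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_attr <- function(key) {
    pat <- sprintf("^# %s=", key)
    hit <- grep(pat, hdr, value = TRUE)
    if (!length(hit))
      stop(sprintf("world file '%s' lacks required attribute '%s'",
                   path, key))
    sub(pat, "", hit[1L])
  }
  age <- as.numeric(get_attr("age_ma"))
  n_lat <- as.integer(get_attr("n_lat"))
  n_lon <- as.integer(get_attr("n_lon"))
  lat <- as.numeric(strsplit(get_attr("lat"), ",")[[1L]])
  lon <- as.numeric(strsplit(get_attr("lon"), ",")[[1L]])
  if (length(lat) != n_lat || length(lon) != n_lon)
    stop("world file header is inconsistent with its grid dimensions")

  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  need <- c("lat_idx", "lon_idx", "landmask", "bathymetry",
            sprintf("sst_%02d", 1:12))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("world file '%s' lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  if (nrow(df) != n_lat * n_lon)
    stop("world file has the wrong number of cell rows")

  grid <- grid_from_centers(lat, lon)

  ord <- order(df$lon_idx, df$lat_idx)     # column-major
  df <- df[ord, ]
  lm_raw <- df$landmask
  if (is.logical(lm_raw)) lm <- lm_raw
  else if (all(lm_raw %in% c(0, 1))) lm <- lm_raw == 1
  else stop("landmask must be logical or 0/1")
  landmask <- matrix(lm, n_lat, n_lon)
  bathymetry <- matrix(df$bathymetry, n_lat, n_lon)
  sst <- array(NA_real_, c(n_lat, n_lon, 12L))
  for (m in 1:12) sst[, , m] <- matrix(df[[sprintf("sst_%02d", m)]],
                                       n_lat, n_lon)
  world_slice(grid, age, landmask, bathymetry, sst)
}
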