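#' Regular lon/lat grid for interpolation
#'
#' @param lon_min,lat_min Lower-left corner of the grid extent (degrees).
#' @param cell_size Cell edge length in degrees (> 0); default 0.1.
#' @param n_cols,n_rows Grid dimensions.
#' @return A `tm_grid` with per-cell centroid coordinates. Cells are indexed
#'   column-major: `cell = (row - 1) * n_cols + col`.
#' @export
make_grid <- function(lon_min, lat_min, cell_size = 0.1, n_cols, n_rows) {
  if (cell_size <= 0) stop_tm("cell_size must be > 0",
                              class = "tempmort_config_error")
  stopifnot(n_cols >= 1, n_rows >= 1)
  col <- rep(seq_len(n_cols), times = n_rows)
  row <- rep(seq_len(n_rows), each = n_cols)
  centroids <- data.frame(
    cell = seq_len(n_cols * n_rows), col = col, row = row,
    lon = lon_min + (col - 0.5) * cell_size,
    lat = lat_min + (row - 0.5) * cell_size)
  structure(list(lon_min = lon_min, lat_min = lat_min, cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 centroids = centroids), class = "tm_grid")
}

#' @export
print.tm_grid <- function(x, ...) {
  cat(sprintf("Grid: %d x %d cells of %g deg from (%g, %g)\n",
              x$n_cols, x$n_rows, x$cell_size, x$lon_min, x$lat_min))
  invisible(x)
}

#' Region mask: the set of grid cells belonging to one region
#'
#' @param region_id Region identifier.
#' @param cells Integer vector of cell indices into `grid$centroids$cell`.
#' @param grid The `tm_grid` the indices refer to.
#' @return A `tm_mask`.
#' @export
region_mask <- function(region_id, cells, grid) {
  cells <- unique(as.integer(cells))
  if (length(cells) == 0L)
    stop_tm("region '%s' has an empty cell set", region_id,
            class = "tempmort_invalid_region")
  if (any(cells < 1L | cells > nrow(grid$centroids)))
    stop_tm("region '%s' has cell indices outside the grid", region_id,
            class = "tempmort_invalid_region")
  structure(list(region_id = as.character(region_id), cells = cells),
            class = "tm_mask")
}

# ray casting point-in-polygon; poly = matrix with lon, lat columns,
# implicitly closed. Boundary points are treated as inside.
point_in_polygon <- function(lon, lat, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Rasterize a polygon to a grid mask by centroid membership
#'
#' A cell belongs to the region when its centroid falls inside the polygon
#' (ray-casting test).
#'
#' @param region_id Region identifier.
#' @param poly Two-column matrix of lon/lat vertices.
#' @param grid A `tm_grid`.
#' @return A `tm_mask`.
#' @export
mask_from_polygon <- function(region_id, poly, grid) {
  cc <- grid$centroids
  region_mask(region_id, cc$cell[point_in_polygon(cc$lon, cc$lat, poly)], grid)
}

#' Read region masks from GeoJSON polygons or a mask CSV
#'
#' GeoJSON: a FeatureCollection of Polygon/MultiPolygon features carrying
#' the region id in `properties[[id_property]]`; outer rings are rasterized
#' by centroid membership (holes ignored). Mask CSV: columns
#' `region_id, col, row`.
#'
#' @param path File path (`.json`/`.geojson` or `.csv`).
#' @param grid A `tm_grid`.
#' @param id_property Property naming the region in GeoJSON features.
#' @return List of `tm_mask` objects.
#' @export
read_region_masks <- function(path, grid, id_property = "region_id") {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(lapply(split(df, df$region_id), function(d)
      region_mask(d$region_id[1L],
                  (d$row - 1L) * grid$n_cols + d$col, grid)))
  }
  gj <- jsonlite::read_json(path)
  masks <- list()
  for (feat in gj$features) {
    id <- feat$properties[[id_property]]
    geom <- feat$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1L]]),
      MultiPolygon = lapply(geom$coordinates, `[[`, 1L),
      stop_tm("unsupported geometry type '%s'", geom$type,
              class = "tempmort_config_error"))
    cells <- integer(0)
    for (ring in rings) {
      poly <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
      cc <- grid$centroids
      cells <- c(cells, cc$cell[point_in_polygon(cc$lon, cc$lat, poly)])
    }
    masks[[id]] <- region_mask(id, cells, grid)
  }
  masks
}

# great-circle distance matrix in km: targets x stations
haversine_km <- function(t_lon, t_lat, s_lon, s_lat) {
  geosphere::distm(cbind(t_lon, t_lat), cbind(s_lon, s_lat),
                   fun = geosphere::distHaversine) / 1000
}

#' Inverse-distance-weighted interpolation of one day's station values
#'
#' `value(target) = sum(w_i v_i) / sum(w_i)` with `w_i = d_i^(-power)` and
#' `d_i` the great-circle (haversine) distance in km. A target coincident
#' with a station (`d = 0`) receives that station's value exactly. All
#' stations with non-missing values contribute (no search radius).
#'
#' @param obs Data frame with columns `lon`, `lat`, `value` (one station
#'   per row; `NA` values are dropped).
#' @param targets Data frame with columns `lon`, `lat`.
#' @param power IDW exponent (> 0); default 2.
#' @param date Optional label used in the all-missing error message.
#' @return Numeric vector, one value per target row.
#' @export
idw_interpolate <- function(obs, targets, power = 2, date = NULL) {
  if (power <= 0) stop_tm("power must be > 0", class = "tempmort_config_error")
  obs <- obs[!is.na(obs$value), , drop = FALSE]
  if (nrow(obs) == 0L)
    stop_tm("all stations missing%s",
            if (is.null(date)) "" else paste0(" on ", date),
            class = "tempmort_missing_data")
  d <- haversine_km(targets$lon, targets$lat, obs$lon, obs$lat)
  w <- d^(-power)
  out <- as.vector((w %*% obs$value) / rowSums(w))
  hit <- which(d == 0, arr.ind = TRUE)
  if (nrow(hit)) out[hit[, 1L]] <- obs$value[hit[, 2L]]
  out
}

#' Unweighted zonal mean of gridded values over a region mask
#'
#' @param cell_values Numeric vector over all grid cells.
#' @param mask A `tm_mask`.
#' @return Scalar arithmetic mean over the masked cells.
#' @export
zonal_mean <- function(cell_values, mask) {
  if (!length(mask$cells))
    stop_tm("empty mask for region '%s'", mask$region_id,
            class = "tempmort_invalid_region")
  mean(cell_values[mask$cells])
}

#' Build daily region weather series from station observations
#'
#' For every region-date, each weather variable is interpolated to the
#' region's grid cells by [idw_interpolate()] and averaged by
#' [zonal_mean()]. Station positions are fixed, so the IDW weight matrix is
#' precomputed once and reused for all complete days.
#'
#' @param stations A `station_set` from [generate_stations()], or a data
#'   frame with columns `station, lon, lat, date, tmean, tmax, tmin, rh`.
#' @param grid A `tm_grid`.
#' @param masks List of `tm_mask` objects, one per region.
#' @param dates Optional date vector; defaults to the dates present.
#' @param power IDW exponent.
#' @param vars Weather variables to interpolate.
#' @return Data frame `region_id, date, tmean, tmax, tmin, rh`, sorted by
#'   region then date.
#' @export
build_region_series <- function(stations, grid, masks, dates = NULL,
                                power = 2,
                                vars = c("tmean", "tmax", "tmin", "rh")) {
  obs <- if (inherits(stations, "station_set"))
    station_obs_table(stations) else stations
  obs$date <- as.Date(obs$date)
  if (is.null(dates)) dates <- sort(unique(obs$date))
  dates <- as.Date(dates)
  gaps <- date_gaps(dates)
  if (length(gaps))
    stop_tm("date gap(s): %s", paste(gaps, collapse = ", "),
            class = "tempmort_date_gap")
  missing_days <- dates[!dates %in% obs$date]
  if (length(missing_days))
    stop_tm("no station observations on: %s",
            paste(missing_days, collapse = ", "),
            class = "tempmort_date_gap")

  st <- unique(obs[, c("station", "lon", "lat")])
  st <- st[order(st$station), ]
  cells <- sort(unique(unlist(lapply(masks, `[[`, "cells"))))
  cc <- grid$centroids[cells, ]
  d <- haversine_km(cc$lon, cc$lat, st$lon, st$lat)
  w <- d^(-power)
  wn <- w / rowSums(w)
  zero <- which(d == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    wn[zero[, 1L], ] <- 0
    wn[zero] <- 1
  }

  obs <- obs[order(obs$date, obs$station), ]
  n_st <- nrow(st); n_day <- length(dates)
  out <- vector("list", length(masks))
  vals <- list()
  for (v in vars) {
    m <- matrix(obs[[v]], nrow = n_st, ncol = n_day)  # station x day
    if (anyNA(m)) {
      interp <- matrix(NA_real_, nrow(cc), n_day)
      for (k in seq_len(n_day)) {
        o <- data.frame(lon = st$lon, lat = st$lat, value = m[, k])
        interp[, k] <- idw_interpolate(o, cc, power, date = dates[k])
      }
    } else {
      interp <- wn %*% m  # cells x day
    }
    vals[[v]] <- interp
  }
  for (i in seq_along(masks)) {
    mk <- masks[[i]]
    rows <- match(mk$cells, cells)
    df <- data.frame(region_id = mk$region_id, date = dates)
    for (v in vars)
      df[[v]] <- colMeans(vals[[v]][rows, , drop = FALSE])
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  res[order(res$region_id, res$date), ]
}

#' Read / write the station observation CSV
#'
#' Schema: `station, lon, lat, date, tmean, tmax, tmin, rh`.
#' @param x Station table (or `station_set`).
#' @param path File path.
#' @return The data frame (readers) or `path` invisibly (writers).
#' @export
write_station_csv <- function(x, path) {
  if (inherits(x, "station_set")) x <- station_obs_table(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_station_csv
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}

#' Read / write the daily region-series CSV
#'
#' Schema: `region_id, date, tmean, tmax, tmin, rh` plus `deaths` when
#' mortality has been attached.
#' @param x Region series data frame.
#' @param path File path.
#' @return The data frame (reader) or `path` invisibly (writer).
#' @export
write_region_series_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_region_series_csv
#' @export
read_region_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}
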