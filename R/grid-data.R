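#' Construct a surface/bottom temperature climatology
#'
#' A pair of co-registered 2-D gridded fields of long-term mean sea surface
#' temperature (SST) and sea bottom temperature (SBT), on a regular
#' latitude-longitude grid. Land (or otherwise unavailable) cells are `NA`.
#'
#' Cell geometry is half-open: a point belongs to the cell whose interval
#' `[edge_i, edge_{i+1})` contains it in both latitude and longitude; the
#' northernmost/easternmost edge is closed so the grid boundary is covered.
#'
#' @param sst,sbt numeric matrices (rows = latitude, south to north;
#'   columns = longitude, west to east), degrees Celsius, `NA` = no value.
#' @param lat_edges,lon_edges strictly increasing cell boundary coordinates
#'   in decimal degrees; `length(lat_edges) == nrow(sst) + 1` and similarly
#'   for longitude.
#' @return An object of class `temperature_climatology`.
#' @export
temperature_climatology <- function(sst, sbt, lat_edges, lon_edges) {
  stopifnot(is.matrix(sst), is.matrix(sbt))
  if (!identical(dim(sst), dim(sbt))) {
    stop("SST and SBT grids are not co-registered: dimensions differ")
  }
  if (length(lat_edges) != nrow(sst) + 1L || length(lon_edges) != ncol(sst) + 1L) {
    stop("edge coordinate lengths do not match grid dimensions")
  }
  if (any(diff(lat_edges) <= 0) || any(diff(lon_edges) <= 0)) {
    stop("cell edges must be strictly increasing")
  }
  both <- !is.na(sst) & !is.na(sbt)
  if (any(sbt[both] > sst[both] + 1e-9)) {
    warning("SBT exceeds SST in ", sum(sbt[both] > sst[both] + 1e-9), " cells")
  }
  structure(
    list(sst = sst, sbt = sbt,
         lat_edges = as.numeric(lat_edges), lon_edges = as.numeric(lon_edges)),
    class = "temperature_climatology"
  )
}

#' @export
print.temperature_climatology <- function(x, ...) {
  n_wet <- sum(!is.na(x$sst))
  cat("Temperature climatology:", nrow(x$sst), "x", ncol(x$sst), "cells;",
      n_wet, "wet\n")
  cat("  lat", min(x$lat_edges), "to", max(x$lat_edges),
      "; lon", min(x$lon_edges), "to", max(x$lon_edges), "\n")
  if (n_wet > 0) {
    cat(sprintf("  SST range %.2f to %.2f degC\n",
                min(x$sst, na.rm = TRUE), max(x$sst, na.rm = TRUE)))
  }
  invisible(x)
}

#' Construct a depth- and month-resolved temperature series
#'
#' A 4-D gridded temperature field with dimensions (month-year time index,
#' depth band, latitude, longitude), on the standard depth-band scheme.
#' The per-cell deepest wet band is derived from the missing mask: the
#' temperature at that band stands in for sea bottom temperature (capped at
#' the 2,000 m floor of the scheme).
#'
#' @param temp 4-D numeric array, dimensions `(time, band, lat, lon)`; the
#'   time index runs January of `years[1]` through December of `years[2]`.
#' @param years inclusive integer year coverage, e.g. `c(1940, 2017)`.
#' @param lat_edges,lon_edges strictly increasing cell edges, degrees.
#' @param scheme a [depth_band_scheme()]; `dim(temp)[2]` must equal its
#'   band count.
#' @return An object of class `depth_resolved_series` with a derived
#'   `deepest_wet` matrix (0 for all-land columns).
#' @export
depth_resolved_series <- function(temp, years, lat_edges, lon_edges,
                                  scheme = depth_band_scheme()) {
  stopifnot(is.array(temp), length(dim(temp)) == 4L)
  years <- as.integer(years)
  if (length(years) != 2L || years[2] < years[1]) {
    stop("years must be an inclusive, non-empty c(first, last) pair")
  }
  n_time <- (years[2] - years[1] + 1L) * 12L
  d <- dim(temp)
  if (d[1] != n_time) {
    stop("time dimension (", d[1], ") does not match year coverage (",
         n_time, " months)")
  }
  if (d[2] != scheme$n_bands) {
    stop("depth dimension (", d[2], ") does not match the band scheme (",
         scheme$n_bands, " bands)")
  }
  if (length(lat_edges) != d[3] + 1L || length(lon_edges) != d[4] + 1L) {
    stop("edge coordinate lengths do not match grid dimensions")
  }
  # wetness taken from the first time slice; a band is wet iff it has a value
  wet <- !is.na(temp[1, , , , drop = FALSE])
  dim(wet) <- d[2:4]
  deepest_wet <- apply(wet, c(2, 3), function(col) {
    w <- which(col)
    if (length(w) == 0) 0L else max(w)
  })
  structure(
    list(temp = temp, years = years,
         lat_edges = as.numeric(lat_edges), lon_edges = as.numeric(lon_edges),
         scheme = scheme, deepest_wet = deepest_wet),
    class = "depth_resolved_series"
  )
}

#' @export
print.depth_resolved_series <- function(x, ...) {
  d <- dim(x$temp)
  cat("Depth-resolved temperature series:", d[1], "months x", d[2], "bands x",
      d[3], "x", d[4], "cells\n")
  cat("  years", x$years[1], "-", x$years[2], ";",
      sum(x$deepest_wet > 0), "wet columns\n")
  invisible(x)
}

# Half-open cell lookup shared by both gridded products: index i such that
# edges[i] <= v < edges[i+1], boundary edge closed; NA outside the grid.
locate_cells <- function(v, edges) {
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > length(edges) - 1L] <- NA_integer_
  as.integer(idx)
}

# Month-year to time index for a depth_resolved_series (NA outside coverage).
time_index <- function(year, month, years) {
  t <- (year - years[1]) * 12L + month
  t[is.na(year) | is.na(month) | year < years[1] | year > years[2]] <- NA_integer_
  as.integer(t)
}

#' Write and read gridded temperature products (plain-text format)
#'
#' The gridded products are serialised to a single JSON document holding the
#' cell edges, coverage metadata, and the full-precision temperature values
#' (missing values stored as JSON `null`). The format is plain text,
#' self-describing, and round-trips exactly: `load_climatology(
#' write_climatology(x, p))` reproduces `x` to the last bit.
#'
#' @param clim a [temperature_climatology()].
#' @param path output file path (conventionally `.json`).
#' @return `write_*` return `path` invisibly; `load_*` return the object.
#' @seealso [load_depth_series()] for the 4-D product.
#' @export
write_climatology <- function(clim, path) {
  stopifnot(inherits(clim, "temperature_climatology"))
  obj <- list(
    format = "thermaffin_climatology", version = 1L,
    lat_edges = clim$lat_edges, lon_edges = clim$lon_edges,
    dim = dim(clim$sst),
    sst = as.vector(clim$sst), sbt = as.vector(clim$sbt)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_climatology
#' @export
load_climatology <- function(path) {
  if (!file.exists(path)) stop("cannot read climatology file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "thermaffin_climatology")) {
    stop("not a climatology file (format tag ", deparse(obj$format), "): ", path)
  }
  d <- as.integer(obj$dim)
  sst <- matrix(as.numeric(obj$sst), d[1], d[2])
  sbt <- matrix(as.numeric(obj$sbt), d[1], d[2])
  if (length(obj$sst) != prod(d) || length(obj$sbt) != prod(d)) {
    stop("corrupt climatology file: value count does not match dimensions")
  }
  temperature_climatology(sst, sbt, obj$lat_edges, obj$lon_edges)
}

#' Write a depth-resolved series to the plain-text grid format
#'
#' @param series a [depth_resolved_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_depth_series <- function(series, path) {
  stopifnot(inherits(series, "depth_resolved_series"))
  obj <- list(
    format = "thermaffin_depth_series", version = 1L,
    years = series$years,
    lat_edges = series$lat_edges, lon_edges = series$lon_edges,
    band_edges = series$scheme$band_edges,
    dim = dim(series$temp),
    temp = as.vector(series$temp)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_depth_series
#' @export
load_depth_series <- function(path) {
  if (!file.exists(path)) stop("cannot read depth-series file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "thermaffin_depth_series")) {
    stop("not a depth-series file (format tag ", deparse(obj$format), "): ", path)
  }
  scheme <- depth_band_scheme()
  if (!isTRUE(all.equal(as.numeric(obj$band_edges), scheme$band_edges))) {
    stop("depth coordinate does not match the standard depth-band scheme")
  }
  d <- as.integer(obj$dim)
  if (length(obj$temp) != prod(d)) {
    stop("corrupt depth-series file: value count does not match dimensions")
  }
  temp <- array(as.numeric(obj$temp), dim = d)
  depth_resolved_series(temp, obj$years, obj$lat_edges, obj$lon_edges, scheme)
}
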