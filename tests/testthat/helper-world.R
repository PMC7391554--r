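# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so the suite is deterministic.

tiny_config <- function(seed = 11, ...) {
  world_config(n_lat = 10, n_lon = 10, year_range = c(2000, 2001),
               seed = seed, ...)
}

# A 3x3 hand-built climatology with one land cell, used where exact cell
# values must be known without any generator in the way.
hand_clim <- function() {
  sst <- matrix(c(10, 11, 12,
                  13, NA, 15,
                  16, 17, 18), nrow = 3, byrow = TRUE)
  sbt <- sst - 2
  sbt[2, 2] <- NA
  temperature_climatology(sst, sbt,
                          lat_edges = c(0, 10, 20, 30),
                          lon_edges = c(0, 10, 20, 30))
}

# Minimal record table in the post-QC shape.
rec <- function(lat, lon, depth = 0, month = 6L, year = 2000L,
                species = "sp_a") {
  data.frame(species_id = species, lat = lat, lon = lon, depth_m = depth,
             event_month = as.integer(month), event_year = as.integer(year),
             stringsAsFactors = FALSE)
}

# Brute-force climatology matcher: linear scan over all cells under the
# declared half-open convention (boundary edges closed). Independent of the
# implementation's findInterval-based lookup.
oracle_match_clim <- function(lat, lon, clim) {
  find1 <- function(v, edges) {
    n <- length(edges) - 1
    for (i in seq_len(n)) {
      hi_ok <- if (i == n) v <= edges[i + 1] else v < edges[i + 1]
      if (v >= edges[i] && hi_ok) return(i)
    }
    NA_integer_
  }
  i <- find1(lat, clim$lat_edges)
  j <- find1(lon, clim$lon_edges)
  if (is.na(i) || is.na(j)) {
    return(list(sst = NA_real_, sbt = NA_real_, reason = "outside_grid"))
  }
  sst <- clim$sst[i, j]; sbt <- clim$sbt[i, j]
  reason <- if (is.na(sst) && is.na(sbt)) "land_cell"
            else if (xor(is.na(sst), is.na(sbt))) "no_temperature_value"
            else NA_character_
  list(sst = sst, sbt = sbt, reason = reason)
}

# Brute-force depth-series matcher: linear scans over cells, months, and
# bands; no findInterval, no vectorised array indexing.
oracle_match_series <- function(lat, lon, depth, month, year, series) {
  out <- list(sst = NA_real_, sbt = NA_real_, tad = NA_real_,
              reason = NA_character_, tdepth_reason = NA_character_)
  fail <- function(r, tr = r) {
    out$reason <- r; out$tdepth_reason <- tr; out
  }
  if (is.na(month) || is.na(year)) return(fail("missing_date"))
  tt <- NA_integer_
  k <- 0L
  for (y in series$years[1]:series$years[2]) for (m in 1:12) {
    k <- k + 1L
    if (y == year && m == month) tt <- k
  }
  if (is.na(tt)) return(fail("year_out_of_range"))
  find1 <- function(v, edges) {
    n <- length(edges) - 1
    for (i in seq_len(n)) {
      hi_ok <- if (i == n) v <= edges[i + 1] else v < edges[i + 1]
      if (v >= edges[i] && hi_ok) return(i)
    }
    NA_integer_
  }
  i <- find1(lat, series$lat_edges)
  j <- find1(lon, series$lon_edges)
  if (is.na(i) || is.na(j)) return(fail("outside_grid"))
  deep <- 0L
  for (b in seq_len(dim(series$temp)[2])) {
    if (!is.na(series$temp[1, b, i, j])) deep <- b
  }
  if (deep == 0L) return(fail("land_cell"))
  out$sst <- series$temp[tt, 1, i, j]
  out$sbt <- series$temp[tt, deep, i, j]
  band <- NA_integer_
  edges <- series$scheme$band_edges
  for (b in seq_len(length(edges) - 1)) {
    hi_ok <- if (b == length(edges) - 1) depth <= edges[b + 1] else depth < edges[b + 1]
    if (depth >= edges[b] && hi_ok) band <- b
  }
  if (is.na(band) || band > deep) {
    out$tdepth_reason <- "depth_below_cell_floor"
  } else {
    out$tad <- series$temp[tt, band, i, j]
  }
  out
}
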