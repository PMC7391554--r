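#' Configuration for a synthetic gridded ocean
#'
#' Defines a simple latitudinally structured ocean used to generate the two
#' gridded temperature products with known generating parameters. Sea surface
#' temperature at a cell centre is
#' `sst_equator + sst_gradient * |lat| + cell noise`; temperature declines by
#' `depth_decay` degrees per depth band down the water column, and the
#' monthly product adds a seasonal cosine cycle (peaking in August north of
#' the equator, February south of it) plus interannual noise. Land is laid
#' down as contiguous random blocks so that coarse-cell "mostly land"
#' matching failures occur, as they do against real coastlines.
#'
#' @param n_lat,n_lon grid cell counts (each at least 2).
#' @param lat_range,lon_range grid extent in decimal degrees.
#' @param land_fraction target proportion of land cells, in `[0, 1)`.
#' @param sst_equator mean SST at the equator, degrees Celsius.
#' @param sst_gradient change in SST per degree of absolute latitude
#'   (degC/degree; negative for a poleward decline).
#' @param depth_decay temperature drop per depth band (degC/band, >= 0).
#' @param seasonal_amplitude amplitude of the monthly cycle (degC).
#' @param year_range inclusive years covered by the monthly product.
#' @param noise_sd standard deviation (degC) of both the fixed per-cell
#'   temperature anomaly and the interannual year-to-year anomaly.
#' @param seed integer RNG seed; everything generated from a config is
#'   deterministic given the seed.
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_lat = 20, n_lon = 20,
                         lat_range = c(-90, 90), lon_range = c(-180, 180),
                         land_fraction = 0.3,
                         sst_equator = 28, sst_gradient = -0.35,
                         depth_decay = 1.0, seasonal_amplitude = 4,
                         year_range = c(2000, 2009),
                         noise_sd = 0.5, seed = 1L) {
  if (n_lat < 2 || n_lon < 2) stop("invalid grid counts: n_lat and n_lon must be >= 2")
  if (land_fraction < 0 || land_fraction >= 1) stop("land_fraction must be in [0, 1)")
  year_range <- as.integer(year_range)
  if (length(year_range) != 2 || year_range[2] < year_range[1]) {
    stop("year_range must be a non-empty inclusive c(first, last) pair")
  }
  if (noise_sd < 0 || seasonal_amplitude < 0 || depth_decay < 0) {
    stop("noise_sd, seasonal_amplitude and depth_decay must be non-negative")
  }
  structure(
    list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
         lat_range = lat_range, lon_range = lon_range,
         land_fraction = land_fraction,
         sst_equator = sst_equator, sst_gradient = sst_gradient,
         depth_decay = depth_decay, seasonal_amplitude = seasonal_amplitude,
         year_range = year_range, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "world_config"
  )
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic shared fields (land mask, bathymetry, per-cell anomaly,
# climatological SST mean). Both gridded products are derived from the same
# fields so they describe the same ocean. Draw order is fixed: mask,
# bathymetry, cell anomaly, then (consumers only) further streams.
synth_fields <- function(config) {
  n_lat <- config$n_lat; n_lon <- config$n_lon
  lat_c <- midpoints(seq(config$lat_range[1], config$lat_range[2], length.out = n_lat + 1))
  lon_c <- midpoints(seq(config$lon_range[1], config$lon_range[2], length.out = n_lon + 1))
  with_seed(config$seed, {
    mask <- matrix(FALSE, n_lat, n_lon)  # TRUE = land
    target <- config$land_fraction
    tries <- 0L
    while (mean(mask) < target && tries < 500L) {
      tries <- tries + 1L
      h <- sample.int(max(1L, n_lat %/% 4L), 1)
      w <- sample.int(max(1L, n_lon %/% 4L), 1)
      i0 <- sample.int(n_lat - h + 1L, 1)
      j0 <- sample.int(n_lon - w + 1L, 1)
      cand <- mask
      cand[i0:(i0 + h - 1L), j0:(j0 + w - 1L)] <- TRUE
      if (any(!cand)) mask <- cand  # never drown the last wet cell
    }
    n_bands <- depth_band_scheme()$n_bands
    bathy <- matrix(0L, n_lat, n_lon)
    bathy[!mask] <- sample.int(n_bands, sum(!mask), replace = TRUE)
    anom <- matrix(stats::rnorm(n_lat * n_lon, 0, config$noise_sd), n_lat, n_lon)
    mu_sst <- config$sst_equator + config$sst_gradient * abs(lat_c) + anom
    list(lat_c = lat_c, lon_c = lon_c,
         lat_edges = seq(config$lat_range[1], config$lat_range[2], length.out = n_lat + 1),
         lon_edges = seq(config$lon_range[1], config$lon_range[2], length.out = n_lon + 1),
         mask = mask, bathy = bathy, mu_sst = mu_sst)
  })
}

midpoints <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Generate a synthetic surface/bottom climatology
#'
#' SST at each wet cell is the configured latitudinal gradient plus a fixed
#' per-cell anomaly; SBT is SST minus `depth_decay` per band down to the
#' cell's (random) deepest wet band, so SBT <= SST everywhere by
#' construction. Land cells are `NA` in both layers.
#'
#' @param config a [world_config()].
#' @return a [temperature_climatology()].
#' @export
make_climatology <- function(config) {
  stopifnot(inherits(config, "world_config"))
  f <- synth_fields(config)
  sst <- f$mu_sst
  sst[f$mask] <- NA_real_
  sbt <- sst - config$depth_decay * pmax(f$bathy - 1L, 0L)
  temperature_climatology(sst, sbt, f$lat_edges, f$lon_edges)
}

#' Generate a synthetic depth- and month-resolved temperature series
#'
#' Monthly temperature at band `b` of a wet cell is the cell's
#' climatological mean, plus a seasonal cosine of the configured amplitude
#' (phase set by hemisphere), plus a per-year interannual anomaly, minus
#' `depth_decay * (b - 1)`. Temperature is therefore non-increasing with
#' band index at every wet cell by construction. Bands below the cell's
#' deepest wet band, and all bands of land columns, are `NA`.
#'
#' @param config a [world_config()].
#' @param scheme a [depth_band_scheme()].
#' @return a [depth_resolved_series()].
#' @export
make_depth_series <- function(config, scheme = depth_band_scheme()) {
  stopifnot(inherits(config, "world_config"))
  f <- synth_fields(config)
  n_lat <- config$n_lat; n_lon <- config$n_lon
  n_years <- config$year_range[2] - config$year_range[1] + 1L
  n_time <- n_years * 12L
  n_bands <- scheme$n_bands
  month <- rep(1:12, n_years)
  yr <- rep(seq_len(n_years), each = 12L)
  # interannual anomaly stream drawn after the shared fields, seeded separately
  # from the config seed so the climatology is unaffected
  yearnoise <- with_seed(config$seed + 1L, {
    array(stats::rnorm(n_years * n_lat * n_lon, 0, config$noise_sd),
          dim = c(n_years, n_lat, n_lon))
  })
  peak <- ifelse(f$lat_c >= 0, 8, 2)  # month of seasonal maximum
  seas <- config$seasonal_amplitude *
    cos(2 * pi * outer(month, peak, `-`) / 12)  # (time, lat)
  base <- array(NA_real_, dim = c(n_time, n_lat, n_lon))
  for (j in seq_len(n_lon)) {
    base[, , j] <- seas + rep(f$mu_sst[, j], each = n_time) +
      yearnoise[yr, , j]
  }
  temp <- array(NA_real_, dim = c(n_time, n_bands, n_lat, n_lon))
  for (b in seq_len(n_bands)) {
    sl <- base - config$depth_decay * (b - 1)
    dry <- f$bathy < b  # (lat, lon): band below the cell floor, or land
    if (any(dry)) sl[rep(dry, each = n_time)] <- NA_real_
    temp[, b, , ] <- sl
  }
  depth_resolved_series(temp, config$year_range, f$lat_edges, f$lon_edges, scheme)
}

#' Generate a complete synthetic world
#'
#' Bundles the climatology, the depth-resolved series (optional, as it is by
#' far the largest object), and the underlying generating fields.
#'
#' @param config a [world_config()].
#' @param include_depth_series build the monthly 4-D product as well?
#' @return An object of class `synthetic_world`.
#' @export
make_world <- function(config, include_depth_series = TRUE) {
  stopifnot(inherits(config, "world_config"))
  w <- list(
    config = config,
    fields = synth_fields(config),
    climatology = make_climatology(config),
    depth_series = if (include_depth_series) make_depth_series(config)
  )
  structure(w, class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world (seed", x$config$seed, "):",
      x$config$n_lat, "x", x$config$n_lon, "cells,",
      round(100 * mean(x$fields$mask), 1), "% land\n")
  invisible(x)
}

#' Default per-species generating parameters
#'
#' Preferred temperatures are drawn uniformly over 4-24 degC — comfortably
#' inside the synthetic ocean's available temperature range so that the
#' occupancy-derived mean is an unbiased estimate of the preference — with a
#' 1.5 degC realised-niche breadth, 200 records per species, and defect
#' rates representative of large occurrence aggregators (depth missing for
#' a large share of records, occasional negative-depth sign conventions,
#' missing or out-of-coverage dates).
#'
#' @param n_species number of species.
#' @param n_per_species records per species.
#' @param groups functional groups to draw from (fish get a habitat).
#' @param seed integer seed for the parameter draw.
#' @return data frame with one row per species: `species_id`, `n`,
#'   `pref_temp`, `niche_sd`, `group`, `fish_habitat`, and the four defect
#'   rates (`depth_missing_rate`, `depth_negative_rate`, `date_missing_rate`,
#'   `year_bad_rate`).
#' @export
species_params <- function(n_species = 50, n_per_species = 200,
                           groups = c("benthos", "macroalgae", "fish"),
                           seed = 1L) {
  with_seed(seed, {
    group <- sample(groups, n_species, replace = TRUE)
    habitat <- ifelse(
      group == "fish",
      sample(c("demersal", "benthopelagic", "pelagic", "reef-associated"),
             n_species, replace = TRUE),
      NA_character_
    )
    data.frame(
      species_id = sprintf("sp_%03d", seq_len(n_species)),
      n = n_per_species,
      pref_temp = stats::runif(n_species, 4, 24),
      niche_sd = 1.5,
      group = group,
      fish_habitat = habitat,
      depth_missing_rate = 0.4,
      depth_negative_rate = 0.02,
      date_missing_rate = 0.05,
      year_bad_rate = 0.01,
      stringsAsFactors = FALSE
    )
  })
}

#' Sample species occurrence records from a synthetic world
#'
#' Records are placed on wet cells with probability proportional to a
#' Gaussian kernel in temperature around the species' preferred temperature,
#' evaluated on the temperature measure appropriate to the species' group
#' (SBT for benthos, macroalgae and demersal/benthopelagic fish; SST
#' otherwise), so the ground-truth affinity is well defined per group.
#' Records are first placed intact, then fields are corrupted at the
#' configured per-species rates: depth set missing, depth sign flipped,
#' date blanked, or year pushed before the gridded product's coverage.
#'
#' @param world a [make_world()] object with at least one wet cell.
#' @param params a [species_params()] data frame.
#' @param seed integer seed for placement and defect injection.
#' @return An object of class `synthetic_occurrences`: a list with
#'   `occurrences` (columns `species_id`, `decimalLatitude`,
#'   `decimalLongitude`, `depth_m`, `eventDate`) and `truth` (per-species
#'   generating parameters; consumed only by tests and validation, never by
#'   the matching pipeline).
#' @export
sample_occurrences <- function(world, params, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  if (all(world$fields$mask)) stop("cannot place occurrences: world is all land")
  clim <- world$climatology
  f <- world$fields
  scheme <- depth_band_scheme()
  lat_w <- diff(f$lat_edges); lon_w <- diff(f$lon_edges)
  sbt_groups <- c("benthos", "macroalgae")
  out <- with_seed(seed, {
    pieces <- vector("list", nrow(params))
    for (k in seq_len(nrow(params))) {
      p <- params[k, ]
      use_sbt <- p$group %in% sbt_groups ||
        (p$group == "fish" && p$fish_habitat %in% c("demersal", "benthopelagic"))
      field <- if (use_sbt) clim$sbt else clim$sst
      wet <- which(!is.na(field))
      tv <- field[wet]
      if (p$niche_sd > 0) {
        wgt <- stats::dnorm(tv, p$pref_temp, p$niche_sd)
      } else {
        wgt <- numeric(length(tv))
      }
      if (sum(wgt) == 0) {  # degenerate niche or kernel underflow: nearest cell(s)
        d <- abs(tv - p$pref_temp)
        wgt <- as.numeric(d == min(d))
      }
      cells <- if (length(wet) == 1L) rep(wet, p$n) else {
        sample(wet, p$n, replace = TRUE, prob = wgt)
      }
      ii <- (cells - 1L) %% nrow(field) + 1L
      jj <- (cells - 1L) %/% nrow(field) + 1L
      lat <- f$lat_edges[ii] + stats::runif(p$n) * lat_w[ii]
      lon <- f$lon_edges[jj] + stats::runif(p$n) * lon_w[jj]
      floor_m <- scheme$band_edges[f$bathy[cells] + 1L]
      depth <- stats::runif(p$n, 0, floor_m)
      year <- sample(seq(world$config$year_range[1], world$config$year_range[2]),
                     p$n, replace = TRUE)
      mon <- sample.int(12L, p$n, replace = TRUE)
      day <- sample.int(28L, p$n, replace = TRUE)
      # defect injection, after placement so the spatial truth stays intact
      depth[stats::runif(p$n) < p$depth_missing_rate] <- NA_real_
      neg <- !is.na(depth) & stats::runif(p$n) < p$depth_negative_rate
      depth[neg] <- -depth[neg]
      bad_year <- stats::runif(p$n) < p$year_bad_rate
      year[bad_year] <- world$config$year_range[1] - sample.int(50L, sum(bad_year), replace = TRUE)
      date <- sprintf("%04d-%02d-%02d", year, mon, day)
      date[stats::runif(p$n) < p$date_missing_rate] <- ""
      pieces[[k]] <- data.frame(
        species_id = p$species_id,
        decimalLatitude = lat, decimalLongitude = lon,
        depth_m = depth, eventDate = date,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, pieces)
  })
  truth <- params[, c("species_id", "pref_temp", "niche_sd", "group",
                      "fish_habitat", "n")]
  structure(list(occurrences = out, truth = truth),
            class = "synthetic_occurrences")
}

#' @export
print.synthetic_occurrences <- function(x, ...) {
  cat("Synthetic occurrences:", nrow(x$occurrences), "records,",
      nrow(x$truth), "species\n")
  invisible(x)
}

#' Generate experimental thermal-limit records with a known generating model
#'
#' For each species with true thermal affinity `x` (its preferred
#' temperature), draws 1 to `max_estimates` upper-limit records with value
#' `a + b*x + c*x^2 + Normal(0, noise_sd)`. A share of records carries a
#' reported standard deviation (uniform on 0.5-2 degC), emulating
#' heterogeneous reporting in thermal-limit compilations.
#'
#' @param truth the `truth` table of a [sample_occurrences()] result (or any
#'   data frame with `species_id`, `pref_temp`, `group`, `fish_habitat`).
#' @param coef generating coefficients `c(a, b, c)` of the quadratic.
#' @param noise_sd residual standard deviation (degC).
#' @param sd_prob probability that a record reports an SD.
#' @param max_estimates maximum records per species (1 forces exactly one).
#' @param seed integer seed.
#' @return data frame with columns `species_id`, `tmax_c`, `tmax_sd`,
#'   `metric`, `group`, `fish_habitat`, `source`, plus the generating
#'   coefficients as attribute `"coef"`.
#' @export
make_thermal_limits <- function(truth, coef = c(15, 1.2, -0.02),
                                noise_sd = 1, sd_prob = 0.5,
                                max_estimates = 3L, seed = 1L) {
  stopifnot(all(c("species_id", "pref_temp") %in% names(truth)))
  with_seed(seed, {
    k <- if (max_estimates > 1L) {
      sample.int(max_estimates, nrow(truth), replace = TRUE)
    } else rep(1L, nrow(truth))
    idx <- rep(seq_len(nrow(truth)), k)
    x <- truth$pref_temp[idx]
    val <- coef[1] + coef[2] * x + coef[3] * x^2 +
      stats::rnorm(length(x), 0, noise_sd)
    sds <- stats::runif(length(x), 0.5, 2)
    sds[stats::runif(length(x)) >= sd_prob] <- NA_real_
    out <- data.frame(
      species_id = truth$species_id[idx],
      tmax_c = val, tmax_sd = sds, metric = "CTmax",
      group = if ("group" %in% names(truth)) truth$group[idx] else NA_character_,
      fish_habitat = if ("fish_habitat" %in% names(truth)) {
        truth$fish_habitat[idx]
      } else NA_character_,
      source = "synthetic",
      stringsAsFactors = FALSE
    )
    attr(out, "coef") <- coef
    out
  })
}
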