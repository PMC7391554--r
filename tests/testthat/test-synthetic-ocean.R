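test_that("config validation rejects impossible worlds", {
  expect_error(world_config(n_lat = 1), "grid counts")
  expect_error(world_config(land_fraction = 1), "land_fraction")
  expect_error(world_config(year_range = c(2005, 2001)), "year_range")
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- tiny_config(seed = 42)
  expect_identical(make_climatology(cfg), make_climatology(cfg))
  expect_identical(make_depth_series(cfg), make_depth_series(cfg))
  w <- make_world(cfg)
  p <- species_params(n_species = 4, n_per_species = 30, seed = 5)
  expect_identical(sample_occurrences(w, p, seed = 9),
                   sample_occurrences(w, p, seed = 9))
  expect_identical(make_thermal_limits(p, seed = 3),
                   make_thermal_limits(p, seed = 3))
})

test_that("land_fraction = 0 yields no missing cells in either layer", {
  clim <- make_climatology(tiny_config(land_fraction = 0))
  expect_false(anyNA(clim$sst))
  expect_false(anyNA(clim$sbt))
})

test_that("cell-centre SST follows the latitudinal generating formula", {
  # noise-free world: SST must equal equator value + gradient * |lat| exactly
  cfg <- tiny_config(sst_gradient = -0.5, sst_equator = 28, noise_sd = 0,
                     land_fraction = 0)
  clim <- make_climatology(cfg)
  lat_c <- (clim$lat_edges[-1] + clim$lat_edges[-11]) / 2
  set.seed(1)
  for (k in 1:20) {
    i <- sample(10, 1); j <- sample(10, 1)
    expect_equal(clim$sst[i, j], 28 - 0.5 * abs(lat_c[i]))
  }
  # with noise, deviations from the formula have roughly the configured SD
  cfg2 <- world_config(n_lat = 40, n_lon = 40, sst_gradient = -0.5,
                       sst_equator = 28, noise_sd = 0.5, land_fraction = 0,
                       seed = 8)
  clim2 <- make_climatology(cfg2)
  lat_c2 <- (clim2$lat_edges[-1] + clim2$lat_edges[-41]) / 2
  resid <- sweep(clim2$sst, 1, 28 - 0.5 * abs(lat_c2))
  expect_gt(sd(resid), 0.4)
  expect_lt(sd(resid), 0.6)
})

test_that("SBT never exceeds SST and depth_decay = 0 gives an isothermal column", {
  clim <- make_climatology(tiny_config())
  both <- !is.na(clim$sst) & !is.na(clim$sbt)
  expect_true(all(clim$sbt[both] <= clim$sst[both]))

  iso <- make_depth_series(tiny_config(depth_decay = 0, seed = 3))
  wet <- which(iso$deepest_wet > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(wet))) {
    i <- wet[k, 1]; j <- wet[k, 2]
    deep <- iso$deepest_wet[i, j]
    expect_equal(iso$temp[, deep, i, j], iso$temp[, 1, i, j])
  }
})

test_that("temperature is non-increasing with band index at every wet cell", {
  s <- make_depth_series(tiny_config(seed = 13))
  wet <- which(s$deepest_wet > 0, arr.ind = TRUE)
  for (k in seq_len(min(nrow(wet), 20))) {
    i <- wet[k, 1]; j <- wet[k, 2]
    col <- s$temp[1, seq_len(s$deepest_wet[i, j]), i, j]
    expect_true(all(diff(col) <= 1e-12))
  }
})

test_that("seasonal_amplitude = 0 makes all months of a year identical", {
  s <- make_depth_series(tiny_config(seasonal_amplitude = 0, seed = 5))
  wet <- which(s$deepest_wet > 0, arr.ind = TRUE)[1, ]
  x <- s$temp[, 1, wet[1], wet[2]]
  for (y in 0:1) {
    months <- x[(y * 12 + 1):(y * 12 + 12)]
    expect_equal(max(months) - min(months), 0)
  }
  # and a nonzero amplitude shows up at full strength
  s2 <- make_depth_series(tiny_config(seasonal_amplitude = 4, noise_sd = 0,
                                      seed = 5))
  x2 <- s2$temp[1:12, 1, wet[1], wet[2]]
  expect_equal(max(x2) - min(x2), 8, tolerance = 0.05)
})

test_that("a wet cell's surface series has the generating climatological mean", {
  # 10 years of months = 120 samples; interannual noise is the only random
  # term after the seasonal cycle averages out, so the series mean must sit
  # within 3 standard errors of the cell's climatological mean
  cfg <- world_config(n_lat = 10, n_lon = 10, year_range = c(2000, 2009),
                      land_fraction = 0, noise_sd = 0.5, seed = 21)
  clim <- make_climatology(cfg)
  s <- make_depth_series(cfg)
  n_months <- dim(s$temp)[1]
  expect_gte(n_months, 120)
  set.seed(2)
  for (k in 1:5) {
    i <- sample(10, 1); j <- sample(10, 1)
    x <- s$temp[, 1, i, j]
    # 10 independent yearly anomalies of sd 0.5: se of the series mean
    se <- cfg$noise_sd / sqrt(10)
    expect_lt(abs(mean(x) - clim$sst[i, j]), 3 * se)
  }
})

test_that("occurrences land on wet cells and defect rates are respected", {
  w <- make_world(tiny_config(seed = 17), include_depth_series = FALSE)
  p <- species_params(n_species = 1, n_per_species = 500, seed = 1)
  p$date_missing_rate <- 0.2
  p$depth_missing_rate <- 0
  p$depth_negative_rate <- 0
  p$year_bad_rate <- 0
  occ <- sample_occurrences(w, p, seed = 99)$occurrences
  # all records on wet cells
  i <- findInterval(occ$decimalLatitude, w$climatology$lat_edges,
                    rightmost.closed = TRUE)
  j <- findInterval(occ$decimalLongitude, w$climatology$lon_edges,
                    rightmost.closed = TRUE)
  expect_false(any(w$fields$mask[cbind(i, j)]))
  # missing-date count within 3 binomial SDs of 100
  n_miss <- sum(occ$eventDate == "")
  expect_lt(abs(n_miss - 100), 3 * sqrt(500 * 0.2 * 0.8))
  # depths all valid when depth defects are off
  expect_true(all(!is.na(occ$depth_m) & occ$depth_m >= 0))
})

test_that("zero defect rates give fully clean records", {
  w <- make_world(tiny_config(seed = 23), include_depth_series = FALSE)
  p <- species_params(n_species = 2, n_per_species = 100, seed = 2)
  p$depth_missing_rate <- 0; p$depth_negative_rate <- 0
  p$date_missing_rate <- 0; p$year_bad_rate <- 0
  occ <- sample_occurrences(w, p, seed = 4)$occurrences
  expect_true(all(occ$depth_m >= 0))
  d <- parse_event_date(occ$eventDate)
  expect_false(anyNA(d$event_month))
  expect_true(all(d$event_year >= 2000 & d$event_year <= 2001))
})

test_that("a degenerate niche concentrates all records in the best cell", {
  w <- make_world(tiny_config(seed = 31), include_depth_series = FALSE)
  p <- species_params(n_species = 1, n_per_species = 50, seed = 1)
  p$group <- "fish"; p$fish_habitat <- "pelagic"; p$niche_sd <- 0
  occ <- sample_occurrences(w, p, seed = 6)$occurrences
  i <- findInterval(occ$decimalLatitude, w$climatology$lat_edges,
                    rightmost.closed = TRUE)
  j <- findInterval(occ$decimalLongitude, w$climatology$lon_edges,
                    rightmost.closed = TRUE)
  cells <- unique(paste(i, j))
  # all records share the single temperature-closest wet cell
  expect_equal(length(cells), 1L)
  best <- which(abs(w$climatology$sst - p$pref_temp) ==
                  min(abs(w$climatology$sst - p$pref_temp), na.rm = TRUE),
                arr.ind = TRUE)
  expect_equal(cells, paste(best[1], best[2]))
})

test_that("an all-land world refuses to place occurrences", {
  w <- make_world(tiny_config(seed = 1), include_depth_series = FALSE)
  w$fields$mask[] <- TRUE
  expect_error(sample_occurrences(w, species_params(1, 10)), "all land")
})

test_that("thermal limits follow the generating quadratic", {
  truth <- data.frame(species_id = c("a", "b", "c"),
                      pref_temp = c(5, 15, 25),
                      group = "benthos", fish_habitat = NA_character_,
                      stringsAsFactors = FALSE)
  # noise-free, one estimate per species: exact quadratic values
  lim <- make_thermal_limits(truth, coef = c(15, 1.2, -0.02), noise_sd = 0,
                             max_estimates = 1L, seed = 2)
  expect_equal(lim$tmax_c, 15 + 1.2 * truth$pref_temp - 0.02 * truth$pref_temp^2)
  # degenerate coefficients: constant limit
  lim0 <- make_thermal_limits(truth, coef = c(10, 0, 0), noise_sd = 0,
                              max_estimates = 1L, seed = 2)
  expect_equal(lim0$tmax_c, rep(10, 3))
})

test_that("thermal-limit noise has the configured spread", {
  n <- 200
  truth <- data.frame(species_id = sprintf("s%03d", 1:n),
                      pref_temp = runif(n, 4, 24),
                      stringsAsFactors = FALSE)
  lim <- make_thermal_limits(truth, coef = c(15, 1.2, -0.02), noise_sd = 1,
                             max_estimates = 1L, seed = 77)
  gen <- 15 + 1.2 * truth$pref_temp - 0.02 * truth$pref_temp^2
  s <- sd(lim$tmax_c - gen)
  # chi-square bounds on the sample SD at n = 200, comfortably inside
  expect_gt(s, 0.85)
  expect_lt(s, 1.15)
})

test_that("generated grids round-trip through the file format", {
  cfg <- tiny_config(seed = 19)
  clim <- make_climatology(cfg)
  s <- make_depth_series(cfg)
  tmp1 <- tempfile(fileext = ".json"); tmp2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(tmp1, tmp2)))
  write_climatology(clim, tmp1)
  write_depth_series(s, tmp2)
  expect_equal(load_climatology(tmp1), clim)
  expect_equal(load_depth_series(tmp2), s)
})
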