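test_that("climatology lookup returns the containing cell's values", {
  clim <- hand_clim()
  r <- rec(lat = c(5, 15, 25), lon = c(5, 25, 15))
  m <- match_climatology(r, clim)
  expect_equal(m$clim_sst, c(10, 15, 17))
  expect_equal(m$clim_sbt, c(8, 13, 15))
  expect_true(all(is.na(m$clim_reason)))
})

test_that("masked and out-of-grid records are excluded with reasons", {
  clim <- hand_clim()
  m <- match_climatology(rec(lat = c(15, 50), lon = c(15, 5)), clim)
  expect_true(all(is.na(m$clim_sst)))
  expect_equal(m$clim_reason, c("land_cell", "outside_grid"))
  # one layer missing: value propagates as missing, reason recorded
  sst <- matrix(10, 2, 2); sbt <- sst - 2; sbt[1, 1] <- NA
  c2 <- temperature_climatology(sst, sbt, c(0, 1, 2), c(0, 1, 2))
  m2 <- match_climatology(rec(lat = 0.5, lon = 0.5), c2)
  expect_equal(m2$clim_sst, 10)
  expect_true(is.na(m2$clim_sbt))
  expect_equal(m2$clim_reason, "no_temperature_value")
})

test_that("points on interior edges go to the half-open lower cell", {
  clim <- hand_clim()
  # lat = 10 is the edge between rows 1 and 2: belongs to row 2's [10, 20)
  m <- match_climatology(rec(lat = c(10, 0, 30), lon = c(5, 5, 5)), clim)
  expect_equal(m$clim_sst, c(13, 10, 16))  # boundary edges closed at 0 and 30
  for (pt in list(c(10, 5), c(0, 5), c(30, 5), c(19.999, 20), c(5, 30))) {
    o <- oracle_match_clim(pt[1], pt[2], clim)
    got <- match_climatology(rec(lat = pt[1], lon = pt[2]), clim)
    expect_identical(got$clim_sst, o$sst)
    expect_identical(got$clim_reason, o$reason)
  }
})

make_small_series <- function(seed = 4) {
  make_depth_series(world_config(n_lat = 6, n_lon = 6, seed = seed,
                                 year_range = c(2000, 2001),
                                 land_fraction = 0.3))
}

test_that("depth-series matching extracts SST, SBT and T-at-depth correctly", {
  s <- make_small_series()
  wet <- which(s$deepest_wet == 27L, arr.ind = TRUE)
  expect_gt(nrow(wet), 0)  # the seeded world has a full-depth cell
  i <- wet[1, 1]; j <- wet[1, 2]
  lat <- (s$lat_edges[i] + s$lat_edges[i + 1]) / 2
  lon <- (s$lon_edges[j] + s$lon_edges[j + 1]) / 2
  m <- match_depth_series(rec(lat, lon, depth = 57, month = 3, year = 2001), s)
  tt <- 12 + 3
  expect_equal(m$grid_sst, s$temp[tt, 1, i, j])
  # a cell wet to 2,000 m: SBT is the deepest band's value
  expect_equal(m$grid_sbt, s$temp[tt, 27, i, j])
  # depth 57 m sits in the [50, 75) band
  expect_equal(m$grid_t_at_depth, s$temp[tt, 6, i, j])
  expect_true(is.na(m$grid_reason))
})

test_that("date and depth exclusions follow the per-product rules", {
  s <- make_small_series()
  wet <- which(s$deepest_wet > 0 & s$deepest_wet < 10, arr.ind = TRUE)
  i <- wet[1, 1]; j <- wet[1, 2]
  lat <- (s$lat_edges[i] + s$lat_edges[i + 1]) / 2
  lon <- (s$lon_edges[j] + s$lon_edges[j + 1]) / 2
  floor_m <- s$scheme$band_edges[s$deepest_wet[i, j] + 1]

  r <- rbind(
    rec(lat, lon, depth = 0, month = NA, year = NA),       # dateless
    rec(lat, lon, depth = 0, month = 1, year = 1939),      # before coverage
    rec(lat, lon, depth = floor_m + 300, month = 1, year = 2000),  # too deep
    rec(lat, lon, depth = 2500, month = 1, year = 2000)    # below scheme floor
  )
  m <- match_depth_series(r, s)
  expect_equal(m$grid_reason[1:2], c("missing_date", "year_out_of_range"))
  expect_true(all(is.na(m$grid_sst[1:2])))
  # deeper-than-cell and deeper-than-scheme records keep SST and SBT
  expect_false(anyNA(m$grid_sst[3:4]))
  expect_false(anyNA(m$grid_sbt[3:4]))
  expect_true(all(is.na(m$grid_t_at_depth[3:4])))
  expect_equal(m$tdepth_reason[3:4], rep("depth_below_cell_floor", 2))
  # a dateless record is still climatology-matchable
  clim <- make_climatology(world_config(n_lat = 6, n_lon = 6, seed = 4,
                                        year_range = c(2000, 2001),
                                        land_fraction = 0.3))
  mc <- match_climatology(r[1, ], clim)
  expect_false(is.na(mc$clim_sst))
})

test_that("matching equals the brute-force oracle on random records", {
  s <- make_small_series(seed = 7)
  clim <- make_climatology(world_config(n_lat = 6, n_lon = 6, seed = 7,
                                        year_range = c(2000, 2001),
                                        land_fraction = 0.3))
  set.seed(55)
  n <- 300
  r <- data.frame(
    species_id = "z",
    lat = runif(n, -95, 95),  # some outside the grid on purpose
    lon = runif(n, -185, 185),
    depth_m = sample(c(0, 10, 57, 200, 1999, 2000, 2500, 3000), n, TRUE),
    event_month = sample(c(NA, 1:12), n, TRUE),
    event_year = sample(c(NA, 1999:2002), n, TRUE),
    stringsAsFactors = FALSE
  )
  r$lon <- ((r$lon + 180) %% 360) - 180
  mc <- match_climatology(r, clim)
  md <- match_depth_series(r, s)
  for (k in seq_len(n)) {
    oc <- oracle_match_clim(r$lat[k], r$lon[k], clim)
    expect_identical(mc$clim_sst[k], oc$sst)
    expect_identical(mc$clim_sbt[k], oc$sbt)
    expect_identical(mc$clim_reason[k], oc$reason)
    os <- oracle_match_series(r$lat[k], r$lon[k], r$depth_m[k],
                              r$event_month[k], r$event_year[k], s)
    expect_identical(md$grid_sst[k], os$sst)
    expect_identical(md$grid_sbt[k], os$sbt)
    expect_identical(md$grid_t_at_depth[k], os$tad)
    expect_identical(md$grid_reason[k], os$reason)
    expect_identical(md$tdepth_reason[k], os$tdepth_reason)
  }
})

test_that("best temperature follows the functional-group rule", {
  groups <- data.frame(
    species_id = c("dem", "pel", "ben", "alg", "brd", "mam", "bpl", "rf",
                   "nek", "unk"),
    group = c("fish", "fish", "benthos", "macroalgae", "birds", "mammals",
              "fish", "fish", "nekton", "plankton"),
    fish_habitat = c("demersal", "pelagic", NA, NA, NA, NA,
                     "benthopelagic", "reef-associated", NA, NA),
    stringsAsFactors = FALSE
  )
  m <- data.frame(species_id = groups$species_id,
                  clim_sst = 20, clim_sbt = 8.2,
                  grid_sst = 19, grid_sbt = 7.5,
                  stringsAsFactors = FALSE)
  out <- assign_best_temperature(m, groups)
  sbt_species <- c("dem", "ben", "alg", "bpl")
  sst_species <- c("pel", "brd", "mam", "rf", "nek")
  expect_equal(out$best_clim[match(sbt_species, out$species_id)], rep(8.2, 4))
  expect_equal(out$best_clim[match(sst_species, out$species_id)], rep(20, 5))
  expect_equal(out$best_grid[match("dem", out$species_id)], 7.5)
  # unknown group: flagged, no best value
  expect_true(is.na(out$best_clim[out$species_id == "unk"]))
  expect_true(out$best_unknown_group[out$species_id == "unk"])
  # nekton override
  out2 <- assign_best_temperature(m, groups, nekton_measure = "sbt")
  expect_equal(out2$best_clim[out2$species_id == "nek"], 8.2)
  # missing component propagates
  m$clim_sbt[m$species_id == "ben"] <- NA
  out3 <- assign_best_temperature(m, groups)
  expect_true(is.na(out3$best_clim[out3$species_id == "ben"]))
})

test_that("the match report conserves counts and recomputes percentages", {
  clim <- hand_clim()
  # 10 records: 8 on wet cells, 2 on the masked cell; 2 of the wet ones dateless
  r <- rbind(
    rec(lat = rep(5, 6), lon = seq(2, 27, length.out = 6)),
    rec(lat = c(25, 25), lon = c(5, 25)),
    rec(lat = c(15, 15), lon = c(15, 15))  # masked cell
  )
  r$event_month[1:2] <- NA; r$event_year[1:2] <- NA
  m <- match_climatology(r, clim)
  rep_ <- match_report(m)
  bm <- rep_$by_measure
  expect_equal(bm$n_matched[bm$measure == "clim_sst"], 8L)
  expect_equal(bm$pct_matched[bm$measure == "clim_sst"], 80)
  # conservation per measure
  for (msr in bm$measure) {
    excl <- sum(rep_$exclusions$n[rep_$exclusions$measure == msr])
    expect_equal(bm$n_total[bm$measure == msr],
                 bm$n_matched[bm$measure == msr] + excl)
  }
  # all-land world: nothing matches anywhere
  land <- temperature_climatology(matrix(NA_real_, 2, 2), matrix(NA_real_, 2, 2),
                                  c(0, 1, 2), c(0, 1, 2))
  ml <- match_climatology(rec(lat = c(0.5, 1.5), lon = c(0.5, 1.5)), land)
  repl <- match_report(ml)
  expect_true(all(repl$by_measure$n_matched == 0))
  expect_true(all(repl$by_measure$pct_matched == 0))
  # per-species flags
  expect_true(all(c("species_id", "matched_any") %in% names(rep_$by_species)))
})
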