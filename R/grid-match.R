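#' Match occurrence records to a surface/bottom climatology
#'
#' Each record is assigned the SST and SBT of the cell containing its
#' coordinates (half-open cell convention, boundary edges closed). No
#' horizontal fallback is attempted: a record on a masked cell is an
#' exclusion, mirroring the coarse-cell failure mode of real products where
#' most of a cell falls on land. Climatology matching never looks at the
#' record's date.
#'
#' @param records data frame of normalised occurrence records (the
#'   `records` element of [read_occurrences()]).
#' @param clim a [temperature_climatology()].
#' @return `records` with columns `clim_sst`, `clim_sbt` (degC or `NA`) and
#'   `clim_reason` (`NA` when both layers matched; otherwise one of
#'   `outside_grid`, `land_cell`, `no_temperature_value`).
#' @export
match_climatology <- function(records, clim) {
  stopifnot(inherits(clim, "temperature_climatology"))
  i <- locate_cells(records$lat, clim$lat_edges)
  j <- locate_cells(records$lon, clim$lon_edges)
  ok <- !is.na(i) & !is.na(j)
  sst <- rep(NA_real_, nrow(records))
  sbt <- rep(NA_real_, nrow(records))
  sst[ok] <- clim$sst[cbind(i[ok], j[ok])]
  sbt[ok] <- clim$sbt[cbind(i[ok], j[ok])]
  reason <- rep(NA_character_, nrow(records))
  reason[!ok] <- "outside_grid"
  reason[ok & is.na(sst) & is.na(sbt)] <- "land_cell"
  reason[ok & xor(is.na(sst), is.na(sbt))] <- "no_temperature_value"
  records$clim_sst <- sst
  records$clim_sbt <- sbt
  records$clim_reason <- reason
  records
}

#' Match occurrence records to the depth-resolved monthly series
#'
#' Records are matched by latitude, longitude, date (month-year) and depth.
#' Three temperatures are extracted per matchable record: SST (surface
#' band), SBT (the cell's deepest wet band — the temperature at 2,000 m
#' where the water column reaches the scheme floor), and temperature at the
#' record's sampling depth. A record with no parseable month/year is
#' excluded from this product (`missing_date`), as is one dated outside the
#' series' coverage (`year_out_of_range`); both remain eligible for
#' climatology matching. Where the sampling depth falls below the cell's
#' deepest wet band (or below the 2,000 m scheme floor), temperature at
#' depth alone is unavailable (`depth_below_cell_floor`) while SST and SBT
#' are still returned.
#'
#' @param records data frame of normalised occurrence records.
#' @param series a [depth_resolved_series()].
#' @return `records` with columns `grid_sst`, `grid_sbt`,
#'   `grid_t_at_depth`, `grid_reason` (whole-product exclusions:
#'   `missing_date`, `year_out_of_range`, `outside_grid`, `land_cell`) and
#'   `tdepth_reason` (additionally `depth_below_cell_floor`).
#' @export
match_depth_series <- function(records, series) {
  stopifnot(inherits(series, "depth_resolved_series"))
  n <- nrow(records)
  sst <- sbt <- tad <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)

  no_date <- is.na(records$event_month) | is.na(records$event_year)
  reason[no_date] <- "missing_date"
  tt <- time_index(records$event_year, records$event_month, series$years)
  bad_year <- !no_date & is.na(tt)
  reason[bad_year] <- "year_out_of_range"

  i <- locate_cells(records$lat, series$lat_edges)
  j <- locate_cells(records$lon, series$lon_edges)
  live <- is.na(reason)
  off <- live & (is.na(i) | is.na(j))
  reason[off] <- "outside_grid"
  live <- is.na(reason)
  deep <- rep(NA_integer_, n)
  deep[live] <- series$deepest_wet[cbind(i[live], j[live])]
  land <- live & deep == 0L
  reason[land] <- "land_cell"
  live <- is.na(reason)

  if (any(live)) {
    sst[live] <- series$temp[cbind(tt[live], 1L, i[live], j[live])]
    sbt[live] <- series$temp[cbind(tt[live], deep[live], i[live], j[live])]
  }
  band <- depth_band_index(records$depth_m, series$scheme)
  has_band <- live & !is.na(band) & band <= deep
  if (any(has_band)) {
    tad[has_band] <- series$temp[cbind(tt[has_band], band[has_band],
                                       i[has_band], j[has_band])]
  }
  tdepth_reason <- reason
  tdepth_reason[live & !has_band] <- "depth_below_cell_floor"

  records$grid_sst <- sst
  records$grid_sbt <- sbt
  records$grid_t_at_depth <- tad
  records$grid_reason <- reason
  records$tdepth_reason <- tdepth_reason
  records
}

# Which temperature layer best represents the water a species experiences.
# SST for birds, mammals, and pelagic and reef-associated fish; SBT for
# benthos, macroalgae, and demersal and benthopelagic fish. Nekton are
# water-column animals with no stated rule; they default to SST, and the
# default can be overridden.
best_measure_for_group <- function(group, fish_habitat = NA_character_,
                                   nekton_measure = c("sst", "sbt")) {
  nekton_measure <- match.arg(nekton_measure)
  out <- rep(NA_character_, length(group))
  out[group %in% c("birds", "mammals")] <- "sst"
  out[group %in% c("benthos", "macroalgae")] <- "sbt"
  out[group == "nekton"] <- nekton_measure
  is_fish <- !is.na(group) & group == "fish"
  out[is_fish & fish_habitat %in% c("pelagic", "reef-associated")] <- "sst"
  out[is_fish & fish_habitat %in% c("demersal", "benthopelagic")] <- "sbt"
  out
}

#' Assign each record its "best" temperature for the species' group
#'
#' Adds `best_clim` and `best_grid`: the SST value for birds, mammals, and
#' pelagic and reef-associated fish, the SBT value for benthos, macroalgae,
#' and demersal and benthopelagic fish. Species with an unknown or
#' unmappable group get no best value and are flagged.
#'
#' @param matched data frame carrying at least `species_id` and whichever of
#'   the `clim_*` / `grid_*` temperature columns have been matched.
#' @param groups data frame with `species_id`, `group`, and (for fish)
#'   `fish_habitat`.
#' @param nekton_measure layer used for the nekton group (no conventional
#'   rule exists; defaults to SST).
#' @return `matched` with `best_clim`, `best_grid`, and logical
#'   `best_unknown_group`.
#' @export
assign_best_temperature <- function(matched, groups,
                                    nekton_measure = c("sst", "sbt")) {
  nekton_measure <- match.arg(nekton_measure)
  m <- match(matched$species_id, groups$species_id)
  grp <- groups$group[m]
  hab <- if ("fish_habitat" %in% names(groups)) groups$fish_habitat[m]
         else rep(NA_character_, length(m))
  best <- best_measure_for_group(grp, hab, nekton_measure)
  pick <- function(sst_col, sbt_col) {
    out <- rep(NA_real_, nrow(matched))
    if (sst_col %in% names(matched)) {
      use <- !is.na(best) & best == "sst"
      out[use] <- matched[[sst_col]][use]
    }
    if (sbt_col %in% names(matched)) {
      use <- !is.na(best) & best == "sbt"
      out[use] <- matched[[sbt_col]][use]
    }
    out
  }
  matched$best_clim <- pick("clim_sst", "clim_sbt")
  matched$best_grid <- pick("grid_sst", "grid_sbt")
  matched$best_unknown_group <- is.na(best)
  matched
}

# Per-measure exclusion reason for an unmatched value. Product-level
# exclusions take priority; a missing value on an otherwise-matched record
# is a missing layer value (or, for temperature at depth, the recorded
# depth falling below the cell floor).
measure_reason <- function(matched, measure) {
  product_reason <- switch(
    measure,
    clim_sst = , clim_sbt = , best_clim = matched$clim_reason,
    grid_sst = , grid_sbt = , best_grid = matched$grid_reason,
    grid_t_at_depth = matched$tdepth_reason,
    stop("unknown measure: ", measure)
  )
  value <- matched[[measure]]
  reason <- rep(NA_character_, nrow(matched))
  unmatched <- is.na(value)
  reason[unmatched] <- product_reason[unmatched]
  if (measure %in% c("best_clim", "best_grid")) {
    reason[unmatched & matched$best_unknown_group] <- "unknown_group"
  }
  reason[unmatched & is.na(reason)] <- "no_temperature_value"
  reason
}

#' Tabulate match success and exclusions per temperature measure
#'
#' Produces the accounting behind a matched run: for every temperature
#' measure present in `matched`, the number and percentage of records
#' matched, a breakdown of exclusions by reason, and a per-species flag for
#' whether the species matched at least once on each measure. The counts
#' are conservative by construction:
#' `n_total = n_matched + sum(n_excluded by reason)` for every measure.
#'
#' @param matched data frame from the matching steps (any subset of the
#'   temperature columns may be present).
#' @return list of class `match_report`: `by_measure` (measure, `n_total`,
#'   `n_matched`, `pct_matched`), `exclusions` (measure, reason, `n`), and
#'   `by_species` (species_id, measure, `n_matched`, `matched_any`).
#' @export
match_report <- function(matched) {
  measures <- intersect(
    c("clim_sst", "clim_sbt", "best_clim",
      "grid_sst", "grid_sbt", "grid_t_at_depth", "best_grid"),
    names(matched)
  )
  if (length(measures) == 0) stop("no temperature measure columns in input")
  n <- nrow(matched)
  by_measure <- do.call(rbind, lapply(measures, function(m) {
    n_matched <- sum(!is.na(matched[[m]]))
    data.frame(measure = m, n_total = n, n_matched = n_matched,
               pct_matched = if (n > 0) 100 * n_matched / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  exclusions <- do.call(rbind, lapply(measures, function(m) {
    r <- measure_reason(matched, m)
    tb <- table(r[!is.na(r)])
    if (length(tb) == 0) return(NULL)
    data.frame(measure = m, reason = names(tb), n = as.integer(tb),
               stringsAsFactors = FALSE)
  }))
  if (is.null(exclusions)) {
    exclusions <- data.frame(measure = character(), reason = character(),
                             n = integer(), stringsAsFactors = FALSE)
  }
  sp <- unique(matched$species_id)
  by_species <- do.call(rbind, lapply(measures, function(m) {
    cnt <- tapply(!is.na(matched[[m]]), matched$species_id, sum)
    data.frame(species_id = names(cnt), measure = m,
               n_matched = as.integer(cnt), matched_any = as.integer(cnt) > 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(by_measure = by_measure, exclusions = exclusions,
                 by_species = by_species),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("Match report\n")
  for (k in seq_len(nrow(x$by_measure))) {
    r <- x$by_measure[k, ]
    cat(sprintf("  %-16s %d / %d matched (%.1f%%)\n",
                r$measure, r$n_matched, r$n_total, r$pct_matched))
  }
  invisible(x)
}
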