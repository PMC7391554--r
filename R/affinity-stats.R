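#' Summarise matched temperatures into per-species thermal affinities
#'
#' For each species and each requested temperature measure, computes the
#' distributional summary of the matched temperatures: mean, minimum,
#' maximum, median, standard deviation (sample, n-1), median absolute
#' deviation (scaled by 1.4826 for normal consistency), and the 5th and
#' 95th quantiles (linear interpolation between order statistics,
#' `stats::quantile` type 7). Records without a value for the measure are
#' excluded from that measure's affinity; the counts record how many were
#' available. With a single matched record the SD is undefined (`NA`); with
#' none, all statistics are `NA` and only the counts remain.
#'
#' @param matched data frame from the matching steps, one row per record.
#' @param measures temperature measure columns to summarise (defaults to all
#'   present).
#' @param mad_constant scale factor of the MAD (1.4826 by default).
#' @return data frame of class `thermal_affinity`: one row per species x
#'   measure with columns `species_id`, `measure`, `n_total`, `n_matched`,
#'   `mean`, `min`, `max`, `median`, `sd`, `mad`, `q05`, `q95`.
#' @export
summarize_affinity <- function(matched,
                               measures = intersect(
                                 c("clim_sst", "clim_sbt", "best_clim",
                                   "grid_sst", "grid_sbt", "grid_t_at_depth",
                                   "best_grid"),
                                 names(matched)),
                               mad_constant = 1.4826) {
  if (length(measures) == 0) stop("no temperature measure columns to summarise")
  species <- unique(matched$species_id)
  rows <- vector("list", length(species) * length(measures))
  k <- 0L
  for (m in measures) {
    vals_all <- matched[[m]]
    for (sp in species) {
      sel <- matched$species_id == sp
      k <- k + 1L
      rows[[k]] <- summarize_species(vals_all[sel], sp, m, mad_constant)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("thermal_affinity", "data.frame")
  out
}

#' Summary statistics for one species on one measure
#'
#' @param values matched temperature values for the species (may contain
#'   `NA` for unmatched records).
#' @param species_id,measure identifiers carried into the output row.
#' @param mad_constant scale factor of the MAD.
#' @return one-row data frame (see [summarize_affinity()]).
#' @export
summarize_species <- function(values, species_id = NA_character_,
                              measure = NA_character_,
                              mad_constant = 1.4826) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0) {
    return(data.frame(
      species_id = species_id, measure = measure,
      n_total = length(values), n_matched = 0L,
      mean = NA_real_, min = NA_real_, max = NA_real_, median = NA_real_,
      sd = NA_real_, mad = NA_real_, q05 = NA_real_, q95 = NA_real_,
      stringsAsFactors = FALSE
    ))
  }
  q <- unname(stats::quantile(v, c(0.05, 0.95), type = 7))
  data.frame(
    species_id = species_id, measure = measure,
    n_total = length(values), n_matched = n,
    mean = mean(v), min = min(v), max = max(v), median = stats::median(v),
    sd = if (n > 1) stats::sd(v) else NA_real_,
    mad = stats::mad(v, constant = mad_constant),
    q05 = q[1], q95 = q[2],
    stringsAsFactors = FALSE
  )
}

#' Correlations between affinity measures across species
#'
#' Pearson correlations, across species, between chosen (measure, statistic)
#' columns of an affinity table — e.g. mean vs 95th quantile within a
#' measure, or the climatology "best" mean against temperature-at-depth
#' mean. Pairs with fewer than 3 species carrying both values get `NA`.
#'
#' @param affinity a [summarize_affinity()] table.
#' @param pairs data frame with columns `measure_x`, `stat_x`, `measure_y`,
#'   `stat_y`, one row per requested correlation.
#' @return `pairs` with columns `r` (Pearson correlation) and `n` (complete
#'   species pairs) appended.
#' @export
affinity_correlations <- function(affinity, pairs) {
  stopifnot(all(c("measure_x", "stat_x", "measure_y", "stat_y") %in% names(pairs)))
  col <- function(measure, stat) {
    sub <- affinity[affinity$measure == measure, c("species_id", stat)]
    stats::setNames(sub[[stat]], sub$species_id)
  }
  species <- unique(affinity$species_id)
  pairs$r <- NA_real_
  pairs$n <- 0L
  for (k in seq_len(nrow(pairs))) {
    x <- col(pairs$measure_x[k], pairs$stat_x[k])[species]
    y <- col(pairs$measure_y[k], pairs$stat_y[k])[species]
    ok <- !is.na(x) & !is.na(y)
    pairs$n[k] <- sum(ok)
    if (sum(ok) >= 3) pairs$r[k] <- stats::cor(x[ok], y[ok])
  }
  pairs
}
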