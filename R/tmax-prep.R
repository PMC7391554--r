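#' Prefer LT100 over LT0 within a species
#'
#' Some algal thermal-limit compilations report both LT0 and LT100 (the
#' temperatures at which 0% and 100% of individuals are dead). When a
#' species carries both, the LT100 records are the upper limit of interest
#' and the LT0 records are dropped. A species with only LT0 keeps it (there
#' is nothing better), and all other metrics pass through untouched. The
#' operation never removes a species' only record.
#'
#' @param records data frame of thermal-limit records with columns
#'   `species_id`, `tmax_c`, `metric` (and any others, carried through).
#' @return the retained records.
#' @export
select_upper_limit <- function(records) {
  stopifnot(all(c("species_id", "metric") %in% names(records)))
  drop <- rep(FALSE, nrow(records))
  for (sp in unique(records$species_id)) {
    sel <- records$species_id == sp
    mets <- records$metric[sel]
    if (any(mets == "LT100") && any(mets == "LT0")) {
      drop[sel & records$metric == "LT0"] <- TRUE
    }
  }
  records[!drop, , drop = FALSE]
}

#' Aggregate thermal-limit records to one Tmax per species
#'
#' A species with one estimate keeps its value. With several, the mean is
#' weighted by the inverse of each estimate's reported standard deviation
#' (`sum(v/sd) / sum(1/sd)`), giving more weight to more precise estimates.
#' When any estimate of a species lacks an SD the weighting is undefined;
#' the default policy falls back to the unweighted mean for that species
#' (the alternative, `"median_sd"`, assigns missing SDs the median reported
#' SD of that species' records). A reported SD of exactly 0 would give an
#' estimate infinite weight and is treated as missing, with a warning.
#'
#' When a `source` column is present, aggregation is per species per
#' source: the same species measured by two compilations yields two rows.
#'
#' @param records retained thermal-limit records (see
#'   [select_upper_limit()]) with columns `species_id`, `tmax_c`,
#'   optionally `tmax_sd`, `source`, `group`, `fish_habitat`.
#' @param missing_sd policy for species with a mix of reported and missing
#'   SDs: `"unweighted"` (default) or `"median_sd"`.
#' @return data frame of class `species_thermal_limit`: one row per species
#'   (per source) with `species_id`, `tmax`, `n_estimates`, plus `source`,
#'   `group`, `fish_habitat` where available.
#' @export
aggregate_tmax <- function(records, missing_sd = c("unweighted", "median_sd")) {
  missing_sd <- match.arg(missing_sd)
  stopifnot(all(c("species_id", "tmax_c") %in% names(records)))
  sds <- if ("tmax_sd" %in% names(records)) as.numeric(records$tmax_sd)
         else rep(NA_real_, nrow(records))
  zero <- !is.na(sds) & sds <= 0
  if (any(zero)) {
    warning(sum(zero), " estimate(s) report SD = 0; treated as missing SD")
    sds[zero] <- NA_real_
  }
  key <- if ("source" %in% names(records)) {
    paste(records$species_id, records$source, sep = "\r")
  } else records$species_id
  rows <- lapply(unique(key), function(k) {
    sel <- key == k
    v <- records$tmax_c[sel]
    s <- sds[sel]
    tmax <- if (length(v) == 1) {
      v
    } else if (anyNA(s)) {
      if (missing_sd == "unweighted") {
        mean(v)
      } else {
        med <- stats::median(s, na.rm = TRUE)
        if (is.na(med)) mean(v) else {
          s[is.na(s)] <- med
          sum(v / s) / sum(1 / s)
        }
      }
    } else {
      sum(v / s) / sum(1 / s)
    }
    first <- which(sel)[1]
    out <- data.frame(species_id = records$species_id[first],
                      tmax = tmax, n_estimates = length(v),
                      stringsAsFactors = FALSE)
    for (extra in c("source", "group", "fish_habitat")) {
      if (extra %in% names(records)) out[[extra]] <- records[[extra]][first]
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("species_thermal_limit", "data.frame")
  out
}

# raw habitat/group label -> (group, fish_habitat)
.group_map <- list(
  "bathydemersal"    = c("fish", "demersal"),
  "demersal"         = c("fish", "demersal"),
  "benthopelagic"    = c("fish", "benthopelagic"),
  "reef-associated"  = c("fish", "reef-associated"),
  "pelagic-neritic"  = c("fish", "pelagic"),
  "pelagic-oceanic"  = c("fish", "pelagic"),
  "pelagic"          = c("fish", "pelagic"),
  "benthos"          = c("benthos", NA),
  "macroalgae"       = c("macroalgae", NA),
  "birds"            = c("birds", NA),
  "mammals"          = c("mammals", NA),
  "fish"             = c("fish", NA),
  "nekton"           = c("nekton", NA)
)

#' Map raw habitat/group labels to functional groups
#'
#' Applies the merge rules under which sparse categories are pooled:
#' bathydemersal fish join demersal, and pelagic-neritic and
#' pelagic-oceanic fish join a single pelagic category. Non-fish labels
#' (benthos, macroalgae, birds, mammals, nekton) map to themselves. Unknown
#' labels, and species absent from the table, are flagged rather than
#' guessed.
#'
#' @param attr_table data frame with `species_id` and `raw_label` columns.
#' @return data frame with `species_id`, `group`, `fish_habitat`, and
#'   logical `flagged` (label unknown or missing).
#' @export
assign_functional_group <- function(attr_table) {
  stopifnot(all(c("species_id", "raw_label") %in% names(attr_table)))
  lab <- tolower(trimws(as.character(attr_table$raw_label)))
  hit <- .group_map[lab]
  group <- unname(vapply(hit, function(h) if (is.null(h)) NA_character_ else h[1], ""))
  habitat <- unname(vapply(hit, function(h) if (is.null(h)) NA_character_ else h[2], ""))
  data.frame(
    species_id = attr_table$species_id,
    group = group, fish_habitat = habitat,
    flagged = is.na(group),
    stringsAsFactors = FALSE
  )
}

#' Apply targeted data corrections
#'
#' Compilation errors are sometimes found on inspection of sources (for
#' example, an upper limit transcribed from the wrong experiment). Rather
#' than hard-coding species, corrections arrive as a list of edits —
#' `(species_id, field, value, note)` — applied in order, each one logged.
#' Two edits to the same field both apply; the last wins. An edit naming an
#' absent species warns and is logged as unapplied.
#'
#' @param records data frame with a `species_id` column.
#' @param edits list of edits, each a list/row with `species_id`, `field`,
#'   `value`, and optionally `note`; or a data frame with those columns; or
#'   `NULL`/empty for identity.
#' @return `records` with edits applied; the log is attached as attribute
#'   `"edit_log"` (data frame: `species_id`, `field`, `value`, `note`,
#'   `applied`, `n_rows`).
#' @export
apply_data_edits <- function(records, edits = NULL) {
  if (is.null(edits) || (is.data.frame(edits) && nrow(edits) == 0) ||
      length(edits) == 0) {
    attr(records, "edit_log") <- data.frame(
      species_id = character(), field = character(), value = character(),
      note = character(), applied = logical(), n_rows = integer(),
      stringsAsFactors = FALSE)
    return(records)
  }
  if (is.data.frame(edits)) {
    edits <- lapply(seq_len(nrow(edits)), function(k) as.list(edits[k, ]))
  }
  log <- vector("list", length(edits))
  for (k in seq_along(edits)) {
    e <- edits[[k]]
    sel <- records$species_id == e$species_id
    applied <- any(sel) && e$field %in% names(records)
    if (!any(sel)) {
      warning("data edit refers to absent species: ", e$species_id)
    } else if (!e$field %in% names(records)) {
      warning("data edit refers to absent field: ", e$field)
    } else {
      records[[e$field]][sel] <- e$value
    }
    log[[k]] <- data.frame(
      species_id = as.character(e$species_id), field = as.character(e$field),
      value = as.character(e$value),
      note = if (!is.null(e$note)) as.character(e$note) else NA_character_,
      applied = applied, n_rows = sum(sel),
      stringsAsFactors = FALSE)
  }
  attr(records, "edit_log") <- do.call(rbind, log)
  records
}
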