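AFFINITY_MEASURES <- c("clim_sst", "clim_sbt", "best_clim",
                       "grid_sst", "grid_sbt", "grid_t_at_depth", "best_grid")

#' Validate a pipeline run configuration
#'
#' Checks a run configuration (a named list, or a path to a YAML file)
#' before anything is read: required keys present, referenced files exist,
#' requested measures are among the seven defined ones. Cross-file
#' consistency that is tolerable (e.g. species in the limits file missing
#' from the group table) produces warnings, not errors.
#'
#' @param config named list or path to a YAML file. Recognised keys:
#'   `occurrences`, `climatology`, `limits` (required); `depth_series`,
#'   `groups`, `edits`, `measures`, `model_measure`, `margin_measure`,
#'   `nekton_measure`, `exclude_groups`, `out_dir` (optional).
#' @return list of class `config_report` with character vectors `errors`
#'   and `warnings`, plus the parsed `config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      return(structure(list(errors = paste0("config file not found: ", config),
                            warnings = character(), config = NULL),
                       class = "config_report"))
    }
    config <- yaml::read_yaml(config)
  }
  errors <- character()
  warnings <- character()
  for (key in c("occurrences", "climatology", "limits")) {
    if (is.null(config[[key]])) {
      errors <- c(errors, paste0("missing required config key: ", key))
    } else if (!file.exists(config[[key]])) {
      errors <- c(errors, paste0(key, " file not found: ", config[[key]]))
    }
  }
  for (key in c("depth_series", "groups", "edits")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      errors <- c(errors, paste0(key, " file not found: ", config[[key]]))
    }
  }
  for (key in c("measures", "model_measure", "margin_measure")) {
    if (!is.null(config[[key]])) {
      bad <- setdiff(config[[key]], AFFINITY_MEASURES)
      if (length(bad) > 0) {
        errors <- c(errors, paste0(
          "unknown measure(s) in ", key, ": ", paste(bad, collapse = ", "),
          "; valid measures are: ", paste(AFFINITY_MEASURES, collapse = ", ")))
      }
    }
  }
  if (length(errors) == 0 && !is.null(config$groups) &&
      !is.null(config$limits)) {
    lim <- utils::read.csv(config$limits, stringsAsFactors = FALSE)
    grp <- utils::read.csv(config$groups, stringsAsFactors = FALSE)
    if ("species_id" %in% names(lim) && "species_id" %in% names(grp)) {
      missing <- setdiff(lim$species_id, grp$species_id)
      if (length(missing) > 0) {
        warnings <- c(warnings, paste0(
          length(missing), " species in the limits file absent from the ",
          "group table (they will be flagged ungrouped)"))
      }
    }
  }
  structure(list(errors = errors, warnings = warnings, config = config),
            class = "config_report")
}

#' @export
print.config_report <- function(x, ...) {
  cat("Config check:", length(x$errors), "error(s),",
      length(x$warnings), "warning(s)\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Run the full thermal-affinity workflow
#'
#' Ingest, match, summarise, model: reads the occurrence CSV, the gridded
#' temperature products and the thermal-limit inputs; applies record QC and
#' matching; reduces matched temperatures to per-species affinities;
#' aggregates thermal limits and fits the polynomial models, model
#' comparisons, vertices, and safety margins. All outputs are written to
#' `out_dir` as CSV/JSON, and a manifest records the counts at every stage.
#' The run is fully deterministic: the same config and inputs produce
#' byte-identical outputs.
#'
#' @param config named list or YAML path (see [validate_config()]).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return the manifest, invisibly (a named list, also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  report <- validate_config(config)
  if (length(report$errors) > 0) {
    stop("configuration stage failed:\n  ", paste(report$errors, collapse = "\n  "))
  }
  config <- report$config
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- ingest ---------------------------------------------------------------
  qc <- read_occurrences(config$occurrences)
  clim <- load_climatology(config$climatology)
  series <- if (!is.null(config$depth_series)) load_depth_series(config$depth_series)

  limits_raw <- utils::read.csv(config$limits, stringsAsFactors = FALSE)
  groups <- if (!is.null(config$groups)) {
    assign_functional_group(utils::read.csv(config$groups, stringsAsFactors = FALSE))
  } else if (all(c("group") %in% names(limits_raw))) {
    unique(limits_raw[, intersect(c("species_id", "group", "fish_habitat"),
                                  names(limits_raw)), drop = FALSE])
  } else {
    stop("limit aggregation stage failed: no functional groups available ",
         "(provide a groups file or group columns in the limits file)")
  }

  # --- match ----------------------------------------------------------------
  matched <- match_climatology(qc$records, clim)
  if (!is.null(series)) matched <- match_depth_series(matched, series)
  matched <- assign_best_temperature(
    matched, groups,
    nekton_measure = config$nekton_measure %||% "sst")
  report_tbl <- match_report(matched)

  # --- affinity -------------------------------------------------------------
  measures <- config$measures %||%
    intersect(AFFINITY_MEASURES, names(matched))
  affinity <- summarize_affinity(matched, measures = measures)

  # --- thermal limits -------------------------------------------------------
  retained <- select_upper_limit(limits_raw)
  limits <- aggregate_tmax(retained)
  if (!"group" %in% names(limits) ||
      (!is.null(config$groups) && all(is.na(limits$group)))) {
    limits$group <- NULL; limits$fish_habitat <- NULL
  }
  if (!"group" %in% names(limits)) {
    gm <- match(limits$species_id, groups$species_id)
    limits$group <- groups$group[gm]
    if ("fish_habitat" %in% names(groups)) {
      limits$fish_habitat <- groups$fish_habitat[gm]
    }
  }
  edits <- if (!is.null(config$edits)) yaml::read_yaml(config$edits)
  limits <- apply_data_edits(limits, edits)
  edit_log <- attr(limits, "edit_log")

  # --- models ---------------------------------------------------------------
  model_measure <- config$model_measure %||%
    (if ("best_clim" %in% measures) "best_clim" else measures[1])
  aff_mean <- affinity[affinity$measure == model_measure,
                       c("species_id", "mean")]
  model_data <- merge(limits, aff_mean, by = "species_id")
  names(model_data)[names(model_data) == "mean"] <- "affinity"
  model_data <- model_data[!is.na(model_data$affinity), , drop = FALSE]

  fit_or_note <- function(form) {
    tryCatch(fit_polynomial_model(model_data, form = form),
             error = function(e) conditionMessage(e))
  }
  fits <- list(pooled = fit_or_note("pooled"),
               additive = fit_or_note("additive"),
               interaction = fit_or_note("interaction"))
  model_report <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.character(f)) return(list(form = nm, skipped = f))
    list(form = nm, n = f$n, r_squared = f$r_squared,
         residual_df = f$residual_df,
         coefficients = f$coefficients,
         raw_coefficients = raw_coefficients(f),
         vertex = vertex(f))
  })
  names(model_report) <- names(fits)
  comparisons <- list()
  if (inherits(fits$additive, "polynomial_fit") &&
      inherits(fits$interaction, "polynomial_fit")) {
    comparisons$interaction_vs_additive <-
      unclass(compare_models(fits$additive, fits$interaction))
  }
  if (inherits(fits$pooled, "polynomial_fit") &&
      inherits(fits$additive, "polynomial_fit")) {
    comparisons$additive_vs_pooled <-
      unclass(compare_models(fits$pooled, fits$additive))
  }

  # --- margins --------------------------------------------------------------
  margin_measure <- config$margin_measure %||%
    (if ("grid_t_at_depth" %in% measures) "grid_t_at_depth" else model_measure)
  margins <- safety_margins(
    limits, affinity, measure = margin_measure,
    exclude_groups = config$exclude_groups %||% c("birds", "mammals", "nekton"))
  margin_tbl <- if (nrow(margins) > 0) bin_margin_table(margins)

  # --- write ----------------------------------------------------------------
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE, na = "")
  }
  wcsv(matched, "matched.csv")
  wcsv(report_tbl$by_measure, "match_report.csv")
  wcsv(report_tbl$exclusions, "match_exclusions.csv")
  wcsv(affinity, "affinity.csv")
  wcsv(limits, "limits.csv")
  if (!is.null(edit_log) && nrow(edit_log) > 0) wcsv(edit_log, "edit_log.csv")
  wcsv(margins, "margins.csv")
  if (!is.null(margin_tbl)) wcsv(margin_tbl, "margin_table.csv")
  jsonlite::write_json(
    list(models = model_report, comparisons = comparisons,
         model_measure = model_measure, margin_measure = margin_measure),
    file.path(out_dir, "model_report.json"),
    auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")

  manifest <- list(
    package_version = as.character(utils::packageVersion("thermaffin")),
    inputs = config[intersect(names(config),
                              c("occurrences", "climatology", "depth_series",
                                "limits", "groups", "edits"))],
    counts = list(
      rows_in = qc$n_in,
      records = nrow(qc$records),
      rejected = nrow(qc$rejected),
      matched_by_measure = stats::setNames(
        as.list(report_tbl$by_measure$n_matched),
        report_tbl$by_measure$measure),
      species_with_limits = nrow(limits),
      species_modeled = nrow(model_data),
      species_margined = nrow(margins),
      species_omitted_from_margins = length(attr(margins, "omitted"))
    ),
    model_measure = model_measure,
    margin_measure = margin_measure
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
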