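#' Normalise sampling depth
#'
#' Occurrence aggregators record depth inconsistently: usually positive
#' metres below the surface, sometimes negative by sign convention, often
#' missing. Negative and missing depths are both set to 0 (sea surface);
#' non-negative values pass through unchanged. The operation is idempotent.
#'
#' An `assume_sign_error` override instead takes the absolute value of
#' negative depths; it is off by default, as treating every negative value
#' as surface is the conservative reading of mixed sign conventions (a
#' negative value may also flag an intertidal record or a missing value).
#'
#' @param depth_raw numeric vector of raw depths in metres (may contain `NA`).
#' @param assume_sign_error if `TRUE`, negative depths become `abs(depth)`
#'   rather than 0.
#' @return numeric vector of depths, all `>= 0`, no `NA`.
#' @export
normalize_depth <- function(depth_raw, assume_sign_error = FALSE) {
  d <- as.numeric(depth_raw)
  if (assume_sign_error) d <- abs(d) else d <- pmax(d, 0)
  d[is.na(d)] <- 0
  d
}

#' Parse occurrence event dates into month and year
#'
#' Accepts ISO 8601 full dates (`"2003-07-15"`, optionally with a time
#' part), year-month (`"2003-07"`), and bare year (`"2003"`; month left
#' missing, making the record ineligible for month-matched lookup).
#' Anything else — including empty strings and `NA` — yields missing month
#' and year. Missing is a value here, not an error: records keep their
#' place and are merely ineligible for time-resolved matching.
#'
#' @param raw_date character vector of raw date strings.
#' @return data frame with integer columns `event_month` (1-12 or `NA`) and
#'   `event_year` (`NA` when unparseable).
#' @export
parse_event_date <- function(raw_date) {
  s <- trimws(as.character(raw_date))
  n <- length(s)
  month <- rep(NA_integer_, n)
  year <- rep(NA_integer_, n)
  full <- grepl("^\\d{4}-\\d{1,2}-\\d{1,2}([T ].*)?$", s)
  ym <- grepl("^\\d{4}-\\d{1,2}$", s)
  y_only <- grepl("^\\d{4}$", s)
  year[full | ym] <- as.integer(substr(s[full | ym], 1, 4))
  month[full | ym] <- as.integer(sub("^\\d{4}-(\\d{1,2}).*$", "\\1", s[full | ym]))
  year[y_only] <- as.integer(s[y_only])
  bad_month <- !is.na(month) & (month < 1L | month > 12L)
  month[bad_month] <- NA_integer_
  year[bad_month] <- NA_integer_
  data.frame(event_month = month, event_year = year)
}

# Map longitudes onto [-180, 180) by modular arithmetic (standard marine
# convention); latitudes cannot be wrapped and are rejected upstream.
wrap_longitude <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Read and quality-control an occurrence CSV
#'
#' Reads a Darwin-Core-style occurrence table and applies the record-level
#' normalisation rules: latitude/longitude validity (longitude outside
#' \[-180, 180) is wrapped; latitude outside \[-90, 90\] cannot be and is
#' rejected), depth normalisation (negative/missing to 0), and date parsing
#' into month and year (missing dates are kept, flagged only). Every
#' rejected row carries exactly one reason code, and
#' `rows in = records out + rows rejected` always holds.
#'
#' @param path path to a CSV file.
#' @param col_map named list mapping the roles `species_id`, `lat`, `lon`,
#'   `depth`, `date` to column names in the file. `depth` and `date`
#'   columns are optional in the file (treated as all-missing if absent).
#' @param assume_sign_error passed to [normalize_depth()].
#' @return list of class `occurrence_qc`: `records` (data frame with
#'   `species_id`, `lat`, `lon`, `depth_m`, `event_month`, `event_year`),
#'   `rejected` (data frame `row`, `reason`), and `n_in`.
#' @export
read_occurrences <- function(path,
                             col_map = list(species_id = "species_id",
                                            lat = "decimalLatitude",
                                            lon = "decimalLongitude",
                                            depth = "depth_m",
                                            date = "eventDate"),
                             assume_sign_error = FALSE) {
  if (!file.exists(path)) stop("cannot read occurrence file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (role in c("species_id", "lat", "lon")) {
    if (!col_map[[role]] %in% names(raw)) {
      stop("occurrence file is missing required column '", col_map[[role]],
           "' (role: ", role, ")")
    }
  }
  qc_occurrences(raw, col_map, assume_sign_error = assume_sign_error)
}

#' @rdname read_occurrences
#' @param raw a data frame already in memory (same columns as the CSV).
#' @export
qc_occurrences <- function(raw,
                           col_map = list(species_id = "species_id",
                                          lat = "decimalLatitude",
                                          lon = "decimalLongitude",
                                          depth = "depth_m",
                                          date = "eventDate"),
                           assume_sign_error = FALSE) {
  n <- nrow(raw)
  get_col <- function(role, default = NA_character_) {
    nm <- col_map[[role]]
    if (!is.null(nm) && nm %in% names(raw)) as.character(raw[[nm]])
    else rep(default, n)
  }
  species <- get_col("species_id")
  lat_s <- get_col("lat"); lon_s <- get_col("lon")
  depth_s <- get_col("depth"); date_s <- get_col("date")

  reason <- rep(NA_character_, n)
  lat <- suppressWarnings(as.numeric(lat_s))
  lon <- suppressWarnings(as.numeric(lon_s))
  has_lat <- !is.na(lat_s) & nzchar(trimws(lat_s))
  has_lon <- !is.na(lon_s) & nzchar(trimws(lon_s))
  reason[is.na(reason) & (!has_lat | is.na(lat))] <- "lat_unparseable"
  reason[is.na(reason) & (lat < -90 | lat > 90)] <- "lat_out_of_range"
  reason[is.na(reason) & (!has_lon | is.na(lon))] <- "lon_unparseable"
  # depth: empty/missing is fine (normalised to 0); non-numeric text is not
  depth_num <- suppressWarnings(as.numeric(depth_s))
  depth_text <- !is.na(depth_s) & nzchar(trimws(depth_s)) & is.na(depth_num)
  reason[is.na(reason) & depth_text] <- "depth_unparseable"

  keep <- is.na(reason)
  dates <- parse_event_date(date_s[keep])
  records <- data.frame(
    species_id = species[keep],
    lat = lat[keep],
    lon = wrap_longitude(lon[keep]),
    depth_m = normalize_depth(depth_num[keep], assume_sign_error),
    event_month = dates$event_month,
    event_year = dates$event_year,
    stringsAsFactors = FALSE
  )
  rejected <- data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  structure(list(records = records, rejected = rejected, n_in = n),
            class = "occurrence_qc")
}

#' @export
print.occurrence_qc <- function(x, ...) {
  cat("Occurrence QC:", x$n_in, "rows in,", nrow(x$records), "records,",
      nrow(x$rejected), "rejected\n")
  if (nrow(x$rejected) > 0) {
    tb <- table(x$rejected$reason)
    for (r in names(tb)) cat("  ", r, ":", tb[[r]], "\n")
  }
  invisible(x)
}
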