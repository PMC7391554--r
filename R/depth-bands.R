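#' World Ocean Atlas standard depth-band scheme
#'
#' The fixed depth discretisation used by depth-resolved gridded temperature
#' products to 2,000 m: 10 m bands to 50 m, 25 m bands from 50 to 200 m,
#' 50 m bands from 200 to 300 m, 100 m bands from 300 to 1,500 m, and 250 m
#' bands from 1,500 to 2,000 m — 27 bands in total.
#'
#' Bands are half-open `[lower, upper)`; the single exception is the deepest
#' band, which is closed at 2,000 m so that a record at exactly 2,000 m is
#' still assignable.
#'
#' @return An object of class `depth_band_scheme`: a list with `band_edges`
#'   (28 strictly increasing depths in metres, 0 to 2000) and `n_bands` (27).
#' @export
#' @examples
#' sch <- depth_band_scheme()
#' sch$n_bands
#' depth_band_index(c(0, 57, 2000), sch)
depth_band_scheme <- function() {
  edges <- c(
    seq(0, 50, by = 10),
    seq(75, 200, by = 25),
    seq(250, 300, by = 50),
    seq(400, 1500, by = 100),
    seq(1750, 2000, by = 250)
  )
  structure(
    list(band_edges = edges, n_bands = length(edges) - 1L),
    class = "depth_band_scheme"
  )
}

#' @export
print.depth_band_scheme <- function(x, ...) {
  cat("Depth band scheme:", x$n_bands, "bands,",
      min(x$band_edges), "to", max(x$band_edges), "m\n")
  invisible(x)
}

#' Map a sampling depth to its depth band
#'
#' Returns the index `i` such that `band_edges[i] <= depth_m < band_edges[i+1]`,
#' with exactly 2,000 m assigned to the deepest band. Depths below the scheme
#' floor (> 2,000 m) return `NA`: the gridded product does not cover them.
#'
#' @param depth_m numeric vector of non-negative depths in metres. Negative
#'   depths are a precondition violation (they should have been normalised
#'   to 0 beforehand, see [normalize_depth()]) and raise an error.
#' @param scheme a [depth_band_scheme()].
#' @return integer vector of band indices (1-based), `NA` where the depth is
#'   below the scheme floor; `NA` inputs propagate.
#' @export
depth_band_index <- function(depth_m, scheme = depth_band_scheme()) {
  stopifnot(inherits(scheme, "depth_band_scheme"))
  if (any(depth_m < 0, na.rm = TRUE)) {
    stop("negative depth passed to depth_band_index(); normalise depths first")
  }
  edges <- scheme$band_edges
  idx <- findInterval(depth_m, edges, rightmost.closed = TRUE)
  idx[!is.na(depth_m) & depth_m > max(edges)] <- NA_integer_
  as.integer(idx)
}
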