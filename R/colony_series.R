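#' Construct a colony census series
#'
#' A `colony_series` holds one colony's metadata and its ordered census
#' records: one count of active breeding pairs per breeding season. Seasons
#' spanning two calendar years (e.g. 1989--1990) are keyed to the first
#' calendar year, so the Malvinas/Falklands 1989--1990 and 2019--2020 censuses
#' are 30 seasons apart.
#'
#' @param colony_id short character code identifying the colony.
#' @param years integer vector of season years, strictly increasing after
#'   sorting; duplicates are rejected (one count per season).
#' @param counts non-negative numeric vector of breeding pairs, same length as
#'   `years`. Counts may be fractional (interpolated values are).
#' @param name optional full colony name.
#' @param region optional region label (e.g. "Chubut", "Malvinas").
#' @param latitude,longitude optional decimal-degree coordinates (south/west
#'   negative); reporting only.
#' @param source optional character vector of provenance tags per record.
#' @param year_range sanity bound on admissible season years.
#' @return an object of class `colony_series`.
#' @examples
#' im <- colony_series("IM", c(1989, 2019), c(1300000, 100000),
#'                     name = "Islas Malvinas", region = "Malvinas")
#' fit_trend(im)
#' @export
colony_series <- function(colony_id, years, counts, name = colony_id,
                          region = NA_character_, latitude = NA_real_,
                          longitude = NA_real_, source = NA_character_,
                          year_range = c(1950, 2030)) {
  stopifnot(is.character(colony_id), length(colony_id) == 1L, nzchar(colony_id))
  years <- as.numeric(years)
  counts <- as.numeric(counts)
  if (length(years) != length(counts)) {
    stop("`years` and `counts` must have the same length", call. = FALSE)
  }
  if (length(years) < 1L) stop("a colony needs at least one census record", call. = FALSE)
  if (anyNA(years) || anyNA(counts)) stop("census records must not contain NA", call. = FALSE)
  if (any(counts < 0)) {
    stop(sprintf("colony %s: negative breeding-pair count (%s)", colony_id,
                 paste(counts[counts < 0], collapse = ", ")), call. = FALSE)
  }
  if (any(years < year_range[1] | years > year_range[2])) {
    stop(sprintf("colony %s: season year outside [%d, %d]", colony_id,
                 year_range[1], year_range[2]), call. = FALSE)
  }
  if (anyDuplicated(years)) {
    dup <- unique(years[duplicated(years)])
    stop(sprintf("colony %s: duplicate census for season year %s",
                 colony_id, paste(dup, collapse = ", ")), call. = FALSE)
  }
  o <- order(years)
  source <- rep_len(as.character(source), length(years))
  structure(
    list(colony_id = colony_id, name = name, region = region,
         latitude = latitude, longitude = longitude,
         records = data.frame(season_year = years[o],
                              breeding_pairs = counts[o],
                              source = source[o],
                              stringsAsFactors = FALSE)),
    class = "colony_series")
}

#' @export
print.colony_series <- function(x, ...) {
  cat(sprintf("<colony_series> %s (%s)%s\n", x$colony_id, x$name,
              if (is.na(x$region)) "" else paste0(", ", x$region)))
  cat(sprintf("  %d census record(s), %d-%d\n", nrow(x$records),
              min(x$records$season_year), max(x$records$season_year)))
  print(x$records, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.colony_series <- function(x, ...) {
  cbind(colony_id = x$colony_id, x$records, stringsAsFactors = FALSE)
}

#' Number of census records in a series
#' @param x a `colony_series`.
#' @return integer record count.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "colony_series"))
  nrow(x$records)
}

#' Subset the most recent records of a series
#' @param x a `colony_series`.
#' @param window number of most-recent records to keep (>= 1).
#' @return a `colony_series` with only the last `window` records.
#' @export
tail_series <- function(x, window) {
  stopifnot(inherits(x, "colony_series"))
  n <- n_records(x)
  if (window < 1 || window > n) {
    stop(sprintf("colony %s: window %d outside 1..%d records",
                 x$colony_id, window, n), call. = FALSE)
  }
  keep <- seq.int(n - window + 1L, n)
  colony_series(x$colony_id, x$records$season_year[keep],
                x$records$breeding_pairs[keep], name = x$name,
                region = x$region, latitude = x$latitude,
                longitude = x$longitude, source = x$records$source[keep])
}
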