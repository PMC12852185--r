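#' Build a census collection from colony series
#'
#' A `census` is a named list of [colony_series()] objects, one per colony.
#'
#' @param ... `colony_series` objects, or a single list of them.
#' @return an object of class `census`.
#' @export
census <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "colony_series")) xs <- xs[[1]]
  ok <- vapply(xs, inherits, logical(1), what = "colony_series")
  if (!all(ok)) stop("all elements must be colony_series objects", call. = FALSE)
  ids <- vapply(xs, `[[`, character(1), "colony_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate colony ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  names(xs) <- ids
  structure(xs, class = "census")
}

#' @export
print.census <- function(x, ...) {
  nr <- vapply(x, n_records, integer(1))
  cat(sprintf("<census> %d colonies, %d records (%d single, %d two-record, %d with >=3)\n",
              length(x), sum(nr), sum(nr == 1L), sum(nr == 2L), sum(nr >= 3L)))
  invisible(x)
}

#' @export
`[.census` <- function(x, i) {
  structure(unclass(x)[i], class = "census")
}

#' @export
as.data.frame.census <- function(x, ...) {
  do.call(rbind, c(lapply(unclass(x), as.data.frame), list(make.row.names = FALSE)))
}

#' Convert a long-format data frame to a census collection
#'
#' @param df data frame with columns `colony_id`, `season_year`,
#'   `breeding_pairs` and optionally `source`.
#' @param year_range admissible season-year bounds, passed to [colony_series()].
#' @return a `census` object, records sorted by year within each colony.
#' @export
as_census <- function(df, year_range = c(1950, 2030)) {
  need <- c("colony_id", "season_year", "breeding_pairs")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (!"source" %in% names(df)) df$source <- NA_character_
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1 in the file view
  bad <- which(is.na(suppressWarnings(as.numeric(df$season_year))) |
               is.na(suppressWarnings(as.numeric(df$breeding_pairs))))
  if (length(bad)) {
    stop(sprintf("malformed row(s) at line(s) %s: non-numeric year or count",
                 paste(df$.line[bad], collapse = ", ")), call. = FALSE)
  }
  df$season_year <- as.numeric(df$season_year)
  df$breeding_pairs <- as.numeric(df$breeding_pairs)
  neg <- which(df$breeding_pairs < 0)
  if (length(neg)) {
    stop(sprintf("negative breeding_pairs at line(s) %s",
                 paste(df$.line[neg], collapse = ", ")), call. = FALSE)
  }
  key <- paste(df$colony_id, df$season_year)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    lines <- df$.line[key == d]
    stop(sprintf("duplicate census for colony %s, year %s (lines %s)",
                 df$colony_id[key == d][1], df$season_year[key == d][1],
                 paste(lines, collapse = " and ")), call. = FALSE)
  }
  series <- lapply(split(df, factor(df$colony_id, levels = unique(df$colony_id))),
                   function(g) colony_series(as.character(g$colony_id[1]),
                                             g$season_year, g$breeding_pairs,
                                             source = g$source,
                                             year_range = year_range))
  census(series)
}

#' Read a census CSV
#'
#' Reads comma-separated UTF-8 census data with header
#' `colony_id,season_year,breeding_pairs[,source]` into a validated [census()]
#' collection (one series per colony, records year-sorted). Malformed rows,
#' duplicate (colony, year) pairs and negative counts raise errors naming the
#' offending file lines.
#'
#' @param path path to a CSV file.
#' @param year_range admissible season-year bounds.
#' @return a `census` object.
#' @export
read_census <- function(path, year_range = c(1950, 2030)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  as_census(df, year_range = year_range)
}

#' Write a census collection to CSV
#'
#' Counts are serialized with 17 significant digits so that
#' `read_census(write_census(x))` reproduces every double bit-identically.
#'
#' @param x a `census` object (may be empty: a header-only file is written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(x, path) {
  stopifnot(inherits(x, "census"))
  if (length(x) == 0L) {
    writeLines("colony_id,season_year,breeding_pairs,source", path)
    return(invisible(path))
  }
  df <- as.data.frame(x)
  df$breeding_pairs <- sprintf("%.17g", df$breeding_pairs)
  df$season_year <- sprintf("%.17g", df$season_year)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
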