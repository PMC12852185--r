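#' Projection / interpolation configuration
#'
#' @param reference_years years to interpolate national abundance to
#'   (default 1996, 2006, 2016 — the window of highest census coverage).
#' @param projection_year forward-projection year (default 2024); must be at
#'   least the latest reference year.
#' @param recent_lambda_colonies colonies whose full-series growth rates are
#'   dominated by an early colonization boom and whose \eqn{\lambda} is
#'   refitted on the most recent records only (default El Pedral "EP" and
#'   Estancia San Lorenzo "ESL").
#' @param recent_window number of most-recent records in that refit
#'   (default 3).
#' @param recent_from_year earliest target year at which the recent-phase
#'   \eqn{\lambda} replaces the full-series one (default 2016, i.e. used for
#'   2016 and 2024).
#' @param allow_backward allow extrapolation before a colony's first census
#'   (default `FALSE`; backward extrapolation is refused and flagged).
#' @param malvinas_id colony id of the Malvinas/Falklands analytical unit.
#' @return a list of class `projection_config`.
#' @export
projection_config <- function(reference_years = c(1996, 2006, 2016),
                              projection_year = 2024,
                              recent_lambda_colonies = c("EP", "ESL"),
                              recent_window = 3,
                              recent_from_year = 2016,
                              allow_backward = FALSE,
                              malvinas_id = "IM") {
  if (projection_year < max(reference_years)) {
    stop("projection_year must be >= max(reference_years)", call. = FALSE)
  }
  structure(list(reference_years = sort(reference_years),
                 projection_year = projection_year,
                 recent_lambda_colonies = recent_lambda_colonies,
                 recent_window = recent_window,
                 recent_from_year = recent_from_year,
                 allow_backward = allow_backward,
                 malvinas_id = malvinas_id),
            class = "projection_config")
}

#' Interpolate a colony's abundance to a target year
#'
#' Evaluates the exponential trajectory \eqn{N = N_a \lambda^{y - t_a}}
#' anchored at the latest census at or before the target year. A year that
#' coincides with a census returns the observed count exactly. Years before
#' the first census are not extrapolated backward (status
#' `"excluded_backward"`, abundance `NA`) unless `allow_backward = TRUE`, in
#' which case the first census anchors a backward evaluation.
#'
#' @param series a [colony_series()].
#' @param estimate the colony's `colony_trend` (must belong to the same
#'   colony).
#' @param year target year.
#' @param allow_backward override the backward-extrapolation guard.
#' @return a list with `colony_id`, `year`, `abundance`, `status` (one of
#'   `"observed"`, `"interpolated"`, `"projected"`, `"excluded_backward"`)
#'   and `anchor_year`.
#' @examples
#' im <- colony_series("IM", c(1989, 2019), c(1300000, 100000))
#' interpolate_to_year(im, fit_trend(im), 1996)$abundance  # ~714,535
#' @export
interpolate_to_year <- function(series, estimate, year, allow_backward = FALSE) {
  stopifnot(inherits(series, "colony_series"), inherits(estimate, "colony_trend"))
  if (!identical(series$colony_id, estimate$colony_id)) {
    stop(sprintf("estimate for %s does not belong to series %s",
                 estimate$colony_id, series$colony_id), call. = FALSE)
  }
  rec <- series$records
  out <- list(colony_id = series$colony_id, year = year,
              abundance = NA_real_, status = NA_character_,
              anchor_year = NA_real_)
  if (year < rec$season_year[1] && !allow_backward) {
    out$status <- "excluded_backward"
    return(out)
  }
  hit <- which(rec$season_year == year)
  if (length(hit)) {
    out$abundance <- rec$breeding_pairs[hit]
    out$status <- "observed"
    out$anchor_year <- year
    return(out)
  }
  at_or_before <- which(rec$season_year <= year)
  a <- if (length(at_or_before)) max(at_or_before) else 1L  # backward: first census
  out$anchor_year <- rec$season_year[a]
  out$abundance <- rec$breeding_pairs[a] * estimate$lambda^(year - out$anchor_year)
  out$status <- if (year > max(rec$season_year)) "projected" else "interpolated"
  out
}

#' Project a colony's abundance beyond its last census
#'
#' \eqn{N = N_{last} \lambda^{y - t_{last}}}, anchored at the most recent
#' actual census. For years inside the observed span use
#' [interpolate_to_year()].
#'
#' @inheritParams interpolate_to_year
#' @return abundance in breeding pairs (numeric scalar).
#' @export
project_to_year <- function(series, estimate, year) {
  stopifnot(inherits(series, "colony_series"), inherits(estimate, "colony_trend"))
  t_last <- max(series$records$season_year)
  if (year < t_last) {
    stop(sprintf("year %s precedes the last census (%s); use interpolate_to_year()",
                 year, t_last), call. = FALSE)
  }
  n_last <- series$records$breeding_pairs[which.max(series$records$season_year)]
  n_last * estimate$lambda^(year - t_last)
}

#' Refit a colony's growth rate on its most recent records
#'
#' Colonies in an early explosive colonization phase (El Pedral, Estancia San
#' Lorenzo) yield unrealistically high full-series growth rates; their
#' \eqn{\lambda} is recalculated from the last `window` censuses only
#' (two-point for `window = 2`, log-linear otherwise) and flagged as a
#' recent-phase estimate.
#'
#' @param series a [colony_series()] with at least `window` records.
#' @param window number of most-recent records to use (>= 2).
#' @return a `colony_trend` with `recent = TRUE`.
#' @export
recent_lambda <- function(series, window = 3) {
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  fit_trend(tail_series(series, window), recent = TRUE)
}

#' Signed percent change
#'
#' @param before,after abundances; `before` must be positive.
#' @param digits rounding for the reported value; `NULL` (default) returns
#'   the unrounded percentage, `0` matches the integer-percent reporting
#'   style.
#' @return `100 * (after - before) / before`.
#' @examples
#' percent_change(863670, 1280900, digits = 0)  # 48
#' @export
percent_change <- function(before, after, digits = NULL) {
  if (any(before <= 0)) stop("percent change undefined for before <= 0", call. = FALSE)
  pc <- 100 * (after - before) / before
  if (!is.null(digits)) pc <- round(pc, digits)
  pc
}

#' National abundance table for reference and projection years
#'
#' For each target year (the reference years and the projection year of
#' `config`), evaluates every colony with at least two records at that year —
#' observed count if censused that year, anchored interpolation inside the
#' span, forward projection beyond the last census, and exclusion (flagged,
#' contributing zero) before the first census. Colonies listed in
#' `config$recent_lambda_colonies` use their recent-phase \eqn{\lambda} for
#' target years at or after `config$recent_from_year`. Colonies are
#' stratified by record count (exactly 2 vs >= 3) and totals are reported
#' per stratum and nationally, both including and excluding the
#' Malvinas/Falklands unit.
#'
#' @param x a [census()] collection.
#' @param trends matching list of `colony_trend` objects (every colony with
#'   >= 2 records must have one).
#' @param config a [projection_config()].
#' @return an object of class `abundance_summary`: list with `colonies`
#'   (data frame `colony_id, year, abundance, status, stratum, lambda_used`)
#'   and `totals` (data frame per year: stratum subtotals, national totals
#'   with/without the Malvinas unit).
#' @export
national_summary <- function(x, trends, config = projection_config()) {
  stopifnot(inherits(x, "census"), inherits(config, "projection_config"))
  nr <- vapply(x, n_records, integer(1))
  x <- x[nr >= 2L]
  trends <- align_trends(trends, names(x))
  years <- c(config$reference_years, config$projection_year)
  recent_fits <- lapply(x[intersect(config$recent_lambda_colonies, names(x))],
                        recent_lambda, window = config$recent_window)
  rows <- list()
  for (yr in years) {
    for (id in names(x)) {
      est <- trends[[id]]
      if (id %in% names(recent_fits) && yr >= config$recent_from_year) {
        est <- recent_fits[[id]]
      }
      last_year <- max(x[[id]]$records$season_year)
      if (yr > last_year) {
        ab <- project_to_year(x[[id]], est, yr)
        res <- list(abundance = ab, status = "projected")
      } else {
        res <- interpolate_to_year(x[[id]], est, yr,
                                   allow_backward = config$allow_backward)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        colony_id = id, year = yr,
        abundance = ifelse(is.na(res$abundance), 0, res$abundance),
        status = res$status,
        stratum = if (n_records(x[[id]]) >= 3L) "three_plus_record" else "two_record",
        lambda_used = est$lambda, recent = isTRUE(est$recent),
        stringsAsFactors = FALSE)
    }
  }
  colonies <- do.call(rbind, rows)
  totals <- do.call(rbind, lapply(split(colonies, colonies$year), function(g) {
    inc <- g$status != "excluded_backward"
    malv <- g$colony_id == config$malvinas_id
    data.frame(
      year = g$year[1],
      two_record = sum(g$abundance[inc & g$stratum == "two_record" & !malv]),
      three_plus_record = sum(g$abundance[inc & g$stratum == "three_plus_record" & !malv]),
      national_excl_malvinas = sum(g$abundance[inc & !malv]),
      malvinas = sum(g$abundance[inc & malv]),
      national_incl_malvinas = sum(g$abundance[inc]),
      n_excluded_backward = sum(!inc),
      stringsAsFactors = FALSE)
  }))
  rownames(totals) <- NULL
  structure(list(colonies = colonies, totals = totals, config = config),
            class = "abundance_summary")
}

#' @export
print.abundance_summary <- function(x, ...) {
  cat("<abundance_summary> totals (breeding pairs, rounded):\n")
  t <- x$totals
  num <- vapply(t, is.numeric, logical(1)) & names(t) != "year"
  t[num] <- lapply(t[num], round)
  print(t, row.names = FALSE)
  invisible(x)
}
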