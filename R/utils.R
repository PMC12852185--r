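#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so seeded routines never perturb global randomness.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Derive a stage-specific seed from a base seed
#'
#' Combines a run-level seed with a stage name by a small stable string hash,
#' so adding a pipeline stage never perturbs the random streams of earlier
#' stages. Result is always in `[0, 2^31 - 1)`.
#'
#' @param seed integer base seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

#' Parse degree-minute coordinate strings to decimal degrees
#'
#' Accepts strings such as `"40°47'S 64°47'W"`; south and west are
#' returned negative. Used only for reporting, never in trend computation.
#'
#' @param x character vector of coordinate pairs.
#' @return a data frame with `latitude` and `longitude` in decimal degrees.
#' @export
parse_coords <- function(x) {
  one <- function(s) {
    m <- gregexpr("([0-9]+)[^0-9]+([0-9]+)[^0-9NSEW]*([NSEW])", s)
    parts <- regmatches(s, m)[[1]]
    if (length(parts) != 2L) return(c(NA_real_, NA_real_))
    val <- vapply(parts, function(p) {
      g <- regmatches(p, regexec("([0-9]+)[^0-9]+([0-9]+)[^0-9NSEW]*([NSEW])", p))[[1]]
      d <- as.numeric(g[2]) + as.numeric(g[3]) / 60
      if (g[4] %in% c("S", "W")) d <- -d
      d
    }, numeric(1))
    val
  }
  out <- t(vapply(x, one, numeric(2)))
  data.frame(latitude = out[, 1], longitude = out[, 2], row.names = NULL)
}

# shared input checks
check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}
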