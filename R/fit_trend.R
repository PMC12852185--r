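#' Fit a colony population growth trend
#'
#' Fits the discrete-time, density-independent exponential model
#' \eqn{N_t = N_0 \lambda^{t - t_0}} to one colony's census series and returns
#' the finite growth rate \eqn{\lambda} and instantaneous rate
#' \eqn{r = \ln\lambda}. With exactly two records the two-point estimator
#' \eqn{\lambda = (N_t/N_0)^{1/(t-t_0)}} is used and no confidence interval is
#' available; with three or more records, ordinary least squares of
#' \eqn{\ln N_t} on \eqn{t} gives \eqn{r} as the slope (multiplicative,
#' lognormal observation error becomes additive on the log scale), and a
#' residual-bootstrap percentile interval for \eqn{\lambda} can be requested.
#'
#' Zero counts are errors, not data: the log-scale model is undefined at
#' \eqn{N = 0} and no silent offset is applied.
#'
#' @param series a [colony_series()] with at least 2 records and all counts
#'   positive.
#' @param method `"auto"` (two-point for 2 records, log-linear otherwise),
#'   `"two_point"` or `"log_linear"`.
#' @param ci logical; compute a residual-bootstrap confidence interval
#'   (log-linear fits only).
#' @param n_boot number of bootstrap replicates (default 2000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed integer seed for the bootstrap; required when `ci = TRUE` so
#'   intervals are reproducible without hidden global state.
#' @param recent logical flag marking a recent-phase refit (see
#'   [recent_lambda()]).
#' @return an object of class `colony_trend` with components `colony_id`,
#'   `method`, `r`, `lambda`, `var_r` (squared standard error of the slope;
#'   `NA` for two-point fits), `ci_lambda`, `classification`, `n_records`,
#'   `span`, and for log-linear fits the underlying `lm` fit.
#' @seealso [classify_trend()], [bootstrap_ci()], [aggregate_trends()]
#' @examples
#' im <- colony_series("IM", c(1989, 2019), c(1300000, 100000))
#' fit_trend(im)                      # lambda = 0.918, r = -0.0855
#'
#' s <- colony_series("X", 2000:2005, 100 * exp(0.05 * (0:5)))
#' fit_trend(s, ci = TRUE, seed = 1)  # zero residuals: interval width 0
#' @export
fit_trend <- function(series, method = c("auto", "two_point", "log_linear"),
                      ci = FALSE, n_boot = 2000, level = 0.95, seed = NULL,
                      recent = FALSE) {
  stopifnot(inherits(series, "colony_series"))
  method <- match.arg(method)
  n <- n_records(series)
  if (method == "auto") {
    if (n < 2L) {
      stop(sprintf("colony %s: a single census record cannot support a trend",
                   series$colony_id), call. = FALSE)
    }
    method <- if (n == 2L) "two_point" else "log_linear"
  }
  est <- switch(method,
                two_point = fit_two_point(series),
                log_linear = fit_log_linear(series))
  if (ci) {
    if (method != "log_linear") {
      stop("confidence intervals require a log-linear fit (>= 3 records)",
           call. = FALSE)
    }
    est <- bootstrap_ci(series, n_boot = n_boot, level = level, seed = seed)
  }
  est$recent <- isTRUE(recent)
  est
}

check_positive_counts <- function(series) {
  z <- series$records$breeding_pairs <= 0
  if (any(z)) {
    stop(sprintf("colony %s: zero count in year %s; growth rate undefined (log of zero)",
                 series$colony_id,
                 paste(series$records$season_year[z], collapse = ", ")),
         call. = FALSE)
  }
}

new_colony_trend <- function(series, method, r, var_r = NA_real_,
                             ci_lambda = NULL, fit = NULL, boot = NULL) {
  yrs <- series$records$season_year
  est <- structure(
    list(colony_id = series$colony_id, method = method,
         r = r, lambda = exp(r), var_r = var_r, ci_lambda = ci_lambda,
         n_records = length(yrs), span = max(yrs) - min(yrs),
         series = series, fit = fit, boot = boot, recent = FALSE),
    class = "colony_trend")
  est$classification <- classify_trend(est)
  est
}

#' Two-point growth rate estimator
#'
#' \eqn{\lambda = (N_t/N_0)^{1/(t - t_0)}} from exactly two censuses; no
#' confidence interval is computed (the fit is saturated).
#'
#' @param series a [colony_series()] with exactly 2 records, both counts > 0.
#' @return a `colony_trend` (method `"two_point"`).
#' @export
fit_two_point <- function(series) {
  stopifnot(inherits(series, "colony_series"))
  if (n_records(series) != 2L) {
    stop(sprintf("colony %s: two-point estimator needs exactly 2 records, got %d",
                 series$colony_id, n_records(series)), call. = FALSE)
  }
  check_positive_counts(series)
  rec <- series$records
  dt <- rec$season_year[2] - rec$season_year[1]
  if (dt == 0) stop("degenerate input: identical census years", call. = FALSE)
  r <- log(rec$breeding_pairs[2] / rec$breeding_pairs[1]) / dt
  new_colony_trend(series, "two_point", r)
}

#' Log-linear growth rate estimator
#'
#' Ordinary least squares of \eqn{\ln N_t} on year; the slope is \eqn{r} and
#' its squared standard error is the sampling variance `var_r` used by the
#' empirical-Bayes aggregation.
#'
#' @param series a [colony_series()] with at least 3 records, all counts > 0.
#' @return a `colony_trend` (method `"log_linear"`) carrying the `lm` fit.
#' @export
fit_log_linear <- function(series) {
  stopifnot(inherits(series, "colony_series"))
  if (n_records(series) < 3L) {
    stop(sprintf("colony %s: log-linear fit needs >= 3 records, got %d",
                 series$colony_id, n_records(series)), call. = FALSE)
  }
  check_positive_counts(series)
  rec <- series$records
  if (length(unique(rec$season_year)) < 2L) {
    stop("degenerate input: all census years equal", call. = FALSE)
  }
  fit <- stats::lm(log(breeding_pairs) ~ season_year, data = rec)
  r <- unname(stats::coef(fit)[2])
  # squared SE of the slope, computed directly (summary.lm warns on the
  # zero-residual series the synthetic noiseless limit produces)
  x <- rec$season_year
  s2 <- sum(stats::resid(fit)^2) / (length(x) - 2)
  var_r <- s2 / sum((x - mean(x))^2)
  new_colony_trend(series, "log_linear", r, var_r = var_r, fit = fit)
}

#' Residual-bootstrap confidence interval for a log-linear trend
#'
#' Resamples the residuals of the log-linear fit with replacement, adds them
#' back to the fitted log-abundances, re-estimates the slope for each
#' replicate, and returns the percentile interval of \eqn{\lambda = e^r}.
#' Residuals are leverage-adjusted (\eqn{e_i / \sqrt{1 - h_{ii}}}) and
#' re-centered before resampling, the standard recipe that restores their
#' variance to the error variance; raw residuals are available with
#' `residual_type = "raw"`. A perfect exponential series (zero residuals)
#' yields an interval of width zero; a fixed seed gives bit-identical
#' intervals.
#'
#' Note that with very short series the percentile interval is anti-
#' conservative: it behaves like a normal-quantile interval where a
#' t(n - 2) quantile would be needed, so at n = 6 the effective coverage of a
#' nominal 95% interval is about \eqn{P(|t_4| \le 1.96) \approx 0.88}.
#'
#' @inheritParams fit_trend
#' @param residual_type `"adjusted"` (leverage-corrected, centered; default)
#'   or `"raw"`.
#' @return a `colony_trend` with `ci_lambda` set and the replicate
#'   \eqn{\lambda} values in `$boot`.
#' @export
bootstrap_ci <- function(series, n_boot = 2000, level = 0.95, seed = NULL,
                         residual_type = c("adjusted", "raw")) {
  est <- fit_log_linear(series)
  stopifnot(n_boot >= 1, level > 0, level < 1)
  residual_type <- match.arg(residual_type)
  x <- series$records$season_year
  cx <- x - mean(x)
  sxx <- sum(cx^2)
  fitted_log <- unname(stats::fitted(est$fit))
  res <- unname(stats::resid(est$fit))
  if (residual_type == "adjusted") {
    res <- res / sqrt(1 - unname(stats::hatvalues(est$fit)))
    res <- res - mean(res)
  }
  n <- length(x)
  lam_star <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    ystar <- fitted_log + matrix(res[idx], nrow = n)
    exp(colSums(cx * ystar) / sxx)
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(lam_star, c(alpha, 1 - alpha)))
  out <- new_colony_trend(series, "log_linear", est$r, var_r = est$var_r,
                          ci_lambda = ci, fit = est$fit, boot = lam_star)
  out$level <- level
  out
}

#' Classify a colony trend
#'
#' A colony is increasing if \eqn{\lambda > 1}, declining if \eqn{\lambda < 1}
#' and stable if \eqn{\lambda = 1}. With a confidence interval available the
#' call is supported statistically: `positive_significant` when the lower
#' bound exceeds 1, `negative_significant` when the upper bound is below 1,
#' `stable` when the interval contains 1. Without an interval (two-point
#' fits) the sign of `r` gives `positive_unsupported` / `negative_unsupported`
#' (`stable` at exactly r = 0).
#'
#' @param x a `colony_trend`, or a numeric `r` value.
#' @param ci_lambda optional length-2 interval for \eqn{\lambda} when `x` is
#'   numeric.
#' @return a character classification label.
#' @export
classify_trend <- function(x, ci_lambda = NULL) {
  if (inherits(x, "colony_trend")) {
    r <- x$r
    ci_lambda <- x$ci_lambda
  } else {
    r <- x
  }
  if (!is.null(ci_lambda) && !anyNA(ci_lambda)) {
    if (ci_lambda[1] > 1) return("positive_significant")
    if (ci_lambda[2] < 1) return("negative_significant")
    return("stable")
  }
  if (r > 0) return("positive_unsupported")
  if (r < 0) return("negative_unsupported")
  "stable"
}

#' @export
print.colony_trend <- function(x, ...) {
  cat(sprintf("<colony_trend> %s [%s%s]\n", x$colony_id, x$method,
              if (isTRUE(x$recent)) ", recent phase" else ""))
  cat(sprintf("  r = %.4f   lambda = %.4f   (%d records, %d-yr span)\n",
              x$r, x$lambda, x$n_records, x$span))
  if (!is.null(x$ci_lambda)) {
    cat(sprintf("  %g%% CI for lambda: [%.4f, %.4f] (residual bootstrap, %d reps)\n",
                100 * (x$level %||% 0.95), x$ci_lambda[1], x$ci_lambda[2],
                length(x$boot)))
  }
  cat(sprintf("  classification: %s\n", x$classification))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.colony_trend <- function(object, ...) {
  out <- data.frame(colony_id = object$colony_id, method = object$method,
                    n_records = object$n_records, span = object$span,
                    r = object$r, lambda = object$lambda,
                    var_r = object$var_r,
                    ci_low = if (is.null(object$ci_lambda)) NA_real_ else object$ci_lambda[1],
                    ci_high = if (is.null(object$ci_lambda)) NA_real_ else object$ci_lambda[2],
                    classification = object$classification,
                    recent = isTRUE(object$recent),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.colony_trend", "data.frame")
  out
}

#' @export
coef.colony_trend <- function(object, ...) {
  c(r = object$r, lambda = object$lambda)
}

#' @export
confint.colony_trend <- function(object, parm = "lambda", level = NULL, ...) {
  if (is.null(object$ci_lambda)) {
    stop("no confidence interval: two-point fits have none; run bootstrap_ci()",
         call. = FALSE)
  }
  ci <- object$ci_lambda
  if (identical(parm, "r")) ci <- log(ci)
  stats::setNames(ci, c("low", "high"))
}

#' Predict abundance from a fitted colony trend
#'
#' Evaluates the fitted exponential trajectory at the requested years. For a
#' log-linear fit this is the regression line back-transformed from the log
#' scale; for a two-point fit it is \eqn{N_0 \lambda^{t - t_0}} through the
#' two censuses. For anchored interpolation/projection with the backward
#' guard, use [interpolate_to_year()] / [project_to_year()].
#'
#' @param object a `colony_trend`.
#' @param years numeric vector of years.
#' @param ... ignored.
#' @return numeric vector of breeding pairs.
#' @export
predict.colony_trend <- function(object, years, ...) {
  rec <- object$series$records
  if (object$method == "log_linear") {
    exp(unname(stats::predict(object$fit,
                              newdata = data.frame(season_year = years))))
  } else {
    rec$breeding_pairs[1] * object$lambda^(years - rec$season_year[1])
  }
}

#' @export
residuals.colony_trend <- function(object, ...) {
  log(object$series$records$breeding_pairs) -
    log(predict(object, object$series$records$season_year))
}

#' @export
plot.colony_trend <- function(x, log = "y", ...) {
  rec <- x$series$records
  yy <- seq(min(rec$season_year), max(rec$season_year), length.out = 100)
  graphics::plot(rec$season_year, rec$breeding_pairs, log = log,
                 xlab = "season year", ylab = "breeding pairs",
                 main = sprintf("%s: lambda = %.3f", x$colony_id, x$lambda), ...)
  graphics::lines(yy, predict(x, yy), col = "steelblue")
  invisible(x)
}

#' Fit trends for every colony in a census collection
#'
#' Applies [fit_trend()] to each colony with at least two records; colonies
#' with a single record are excluded (with a message) as in the source
#' stratification. Bootstrap intervals are computed for all log-linear fits
#' using per-colony seeds derived from `seed`.
#'
#' @param x a [census()] collection.
#' @param ci compute bootstrap intervals for colonies with >= 3 records.
#' @param n_boot,level,seed see [bootstrap_ci()]; `seed` is fanned out per
#'   colony via [derive_seed()].
#' @return a named list of `colony_trend` objects, class `colony_trends`.
#' @export
fit_trends <- function(x, ci = FALSE, n_boot = 2000, level = 0.95, seed = NULL) {
  stopifnot(inherits(x, "census"))
  nr <- vapply(x, n_records, integer(1))
  if (any(nr < 2L)) {
    message(sprintf("excluding %d single-record colony(ies): %s",
                    sum(nr < 2L), paste(names(x)[nr < 2L], collapse = ", ")))
    x <- x[nr >= 2L]
    nr <- nr[nr >= 2L]
  }
  out <- lapply(x, function(s) {
    want_ci <- ci && n_records(s) >= 3L
    fit_trend(s, ci = want_ci, n_boot = n_boot, level = level,
              seed = if (want_ci && !is.null(seed))
                derive_seed(seed, s$colony_id) else seed)
  })
  structure(out, class = "colony_trends")
}

#' @export
print.colony_trends <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' @export
summary.colony_trends <- function(object, ...) {
  do.call(rbind, c(lapply(unclass(object), summary), list(make.row.names = FALSE)))
}
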