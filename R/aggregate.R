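#' Abundance-by-years colony weights
#'
#' The simple weighting scheme gives each colony weight
#' \eqn{w_i = \bar N_i Y_i}: its mean observed abundance times its number of
#' census years, so larger and better-monitored colonies count for more.
#'
#' @param x a [census()] collection; every colony must have at least 2
#'   records (single-record colonies are excluded upstream).
#' @return a data frame with `colony_id`, `mean_abundance`, `n_years`,
#'   `weight`.
#' @export
simple_weights <- function(x) {
  stopifnot(inherits(x, "census"))
  if (length(x) == 0L) {
    return(data.frame(colony_id = character(), mean_abundance = numeric(),
                      n_years = integer(), weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  nr <- vapply(x, n_records, integer(1))
  if (any(nr < 2L)) {
    stop(sprintf("colony(ies) with < 2 records must be excluded upstream: %s",
                 paste(names(x)[nr < 2L], collapse = ", ")), call. = FALSE)
  }
  nbar <- vapply(x, function(s) mean(s$records$breeding_pairs), numeric(1))
  data.frame(colony_id = names(x), mean_abundance = unname(nbar),
             n_years = unname(nr), weight = unname(nbar * nr),
             stringsAsFactors = FALSE, row.names = NULL)
}

align_trends <- function(trends, ids) {
  have <- vapply(trends, `[[`, character(1), "colony_id")
  names(trends) <- have
  miss <- setdiff(ids, have)
  extra <- setdiff(have, ids)
  if (length(miss) || length(extra)) {
    stop(sprintf("colony sets differ: missing trends for [%s]; trends without weights/series for [%s]",
                 paste(miss, collapse = ", "), paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  trends[ids]
}

new_aggregate_trend <- function(method, r_general, ci_lambda = NULL,
                                variance = NA_real_, n_colonies, components) {
  structure(list(method = method, r_general = r_general,
                 lambda_general = exp(r_general), ci_lambda = ci_lambda,
                 variance = variance, n_colonies = n_colonies,
                 components = components),
            class = "aggregate_trend")
}

#' Simple weighted aggregate growth rate
#'
#' Pools colony growth rates as
#' \eqn{r_{general} = \sum r_i w_i / \sum w_i} with the abundance-by-years
#' weights of [simple_weights()], and \eqn{\lambda_{general} =
#' e^{r_{general}}}. An optional nonparametric bootstrap resamples colonies
#' with replacement and recomputes the weighted mean to give a percentile
#' interval.
#'
#' @param trends a list of [fit_trend()] results (`colony_trends` or plain
#'   list).
#' @param weights data frame from [simple_weights()]; must cover exactly the
#'   same colonies.
#' @param ci logical; bootstrap a percentile interval over colonies.
#' @param n_boot bootstrap replicates (default 1000).
#' @param level confidence level.
#' @param seed integer seed for the colony bootstrap.
#' @return an `aggregate_trend` (method `"simple"`).
#' @examples
#' a <- colony_series("A", c(2000, 2001), c(100, 300))
#' b <- colony_series("B", c(2000, 2002), c(300, 250))
#' cen <- census(a, b)
#' aggregate_simple(fit_trends(cen), simple_weights(cen))
#' @export
aggregate_simple <- function(trends, weights, ci = FALSE, n_boot = 1000,
                             level = 0.95, seed = NULL) {
  trends <- align_trends(trends, weights$colony_id)
  r <- vapply(trends, `[[`, numeric(1), "r")
  w <- weights$weight
  if (any(w <= 0)) stop("non-positive weight", call. = FALSE)
  r_general <- sum(r * w) / sum(w)
  ci_lambda <- NULL
  if (ci) {
    k <- length(r)
    lam_star <- with_seed(seed, {
      idx <- matrix(sample.int(k, k * n_boot, replace = TRUE), nrow = k)
      rs <- matrix(r[idx], nrow = k)
      ws <- matrix(w[idx], nrow = k)
      exp(colSums(rs * ws) / colSums(ws))
    })
    alpha <- (1 - level) / 2
    ci_lambda <- unname(stats::quantile(lam_star, c(alpha, 1 - alpha)))
  }
  comp <- weights
  comp$r <- unname(r)
  new_aggregate_trend("simple", r_general, ci_lambda = ci_lambda,
                      n_colonies = length(r), components = comp)
}

#' Empirical-Bayes shrinkage components
#'
#' Moment-based shrinkage of colony trends toward their mean, for colonies
#' with a sampling variance (log-linear fits, >= 3 records). With colony
#' trends \eqn{t} and variances \eqn{v_t}:
#' \deqn{\tau^2 = \max(V_t - \bar v_t, 0)}
#' where \eqn{V_t} is the sample variance among colony trends and
#' \eqn{\bar v_t} the mean within-colony variance; the Bayesian weight is
#' \eqn{w_{tb} = v_t / (v_t + \tau^2)} and the adjusted trend and variance
#' \eqn{t_b = \bar t\, w_{tb} + t (1 - w_{tb})}, \eqn{v_{tb} = w_{tb} \tau^2}.
#' Noisier colonies are shrunk harder; a perfectly measured colony
#' (\eqn{v_t = 0}) is not shrunk at all. When \eqn{\tau^2 = 0} every
#' \eqn{w_{tb} = 1} and all trends collapse to the mean.
#'
#' The abundance weight of colony \eqn{i} is its mean share of the total
#' counted population over its own census years,
#' \eqn{w^A_i = \frac{1}{T_i}\sum_{t \in T_i} C_{i,t} / \sum_j C_{j,t}},
#' with the denominator summing the counts of all colonies observed in year
#' \eqn{t} (unobserved counts are unknown, not zero); the \eqn{w^A} are then
#' renormalized to sum to exactly 1.
#'
#' @param trends list of `colony_trend` objects, all with `var_r` (log-linear).
#' @param x the [census()] collection for the same colonies (provides the
#'   counts behind \eqn{w^A}).
#' @return an object of class `eb_components`: a per-colony data frame
#'   (`colony_id`, `t`, `var_t`, `bayes_weight`, `shrunk_trend`,
#'   `shrunk_var`, `abundance_weight`) plus globals `mean_trend`,
#'   `among_var`, `mean_within_var`, `tau2`.
#' @export
eb_shrink <- function(trends, x) {
  stopifnot(inherits(x, "census"))
  trends <- align_trends(trends, names(x))
  if (length(trends) < 2L) {
    stop("empirical-Bayes shrinkage needs >= 2 colonies (among-colony variance undefined)",
         call. = FALSE)
  }
  t_i <- vapply(trends, `[[`, numeric(1), "r")
  v_i <- vapply(trends, `[[`, numeric(1), "var_r")
  if (anyNA(v_i)) {
    stop(sprintf("missing trend variance for colony(ies) %s: empirical-Bayes requires log-linear fits (>= 3 records)",
                 paste(names(trends)[is.na(v_i)], collapse = ", ")), call. = FALSE)
  }
  t_bar <- mean(t_i)
  V_t <- stats::var(t_i)          # n - 1 denominator
  v_bar <- mean(v_i)
  tau2 <- max(V_t - v_bar, 0)
  w_tb <- if (tau2 == 0) rep(1, length(t_i)) else v_i / (v_i + tau2)
  t_b <- t_bar * w_tb + t_i * (1 - w_tb)
  v_tb <- w_tb * tau2

  # abundance weights: mean yearly share of the total counted population
  long <- as.data.frame(x)
  year_tot <- tapply(long$breeding_pairs, long$season_year, sum)
  share <- long$breeding_pairs / year_tot[as.character(long$season_year)]
  wA <- tapply(share, factor(long$colony_id, levels = names(x)), mean)
  wA <- as.numeric(wA / sum(wA))

  structure(
    list(colonies = data.frame(colony_id = names(trends), t = unname(t_i),
                               var_t = unname(v_i), bayes_weight = unname(w_tb),
                               shrunk_trend = unname(t_b),
                               shrunk_var = unname(v_tb),
                               abundance_weight = wA,
                               stringsAsFactors = FALSE, row.names = NULL),
         mean_trend = t_bar, among_var = V_t, mean_within_var = v_bar,
         tau2 = tau2),
    class = "eb_components")
}

#' @export
print.eb_components <- function(x, ...) {
  cat(sprintf("<eb_components> %d colonies; tau2 = %.3g (V_t = %.3g, mean v_t = %.3g)\n",
              nrow(x$colonies), x$tau2, x$among_var, x$mean_within_var))
  print(x$colonies, row.names = FALSE)
  invisible(x)
}

#' Empirical-Bayes aggregate growth rate
#'
#' Pools the shrunk colony trends with the abundance weights:
#' \eqn{r_{general} = \sum w^A t_b} (a weighted average, since the \eqn{w^A}
#' sum to 1), \eqn{\lambda_{general} = e^{r_{general}}}, and a normal-theory
#' interval \eqn{\exp(r_{general} \pm z \sqrt{v})}. The pooled variance is by
#' default the weighted mean of the shrunk variances,
#' \eqn{v = \sum w^A v_{tb}}; `variance = "weighted_sq"` uses
#' \eqn{\sum (w^A)^2 v_{tb}} instead (the variance of the weighted mean under
#' independence).
#'
#' @param components an [eb_shrink()] result.
#' @param variance `"weighted_mean"` (default) or `"weighted_sq"`.
#' @param level confidence level for the normal-theory interval.
#' @return an `aggregate_trend` (method `"empirical_bayes"`).
#' @export
aggregate_eb <- function(components, variance = c("weighted_mean", "weighted_sq"),
                         level = 0.95) {
  stopifnot(inherits(components, "eb_components"))
  variance <- match.arg(variance)
  cc <- components$colonies
  if (abs(sum(cc$abundance_weight) - 1) > 1e-12) {
    stop("internal invariant failure: abundance weights do not sum to 1",
         call. = FALSE)
  }
  r_general <- sum(cc$abundance_weight * cc$shrunk_trend)
  v <- switch(variance,
              weighted_mean = sum(cc$abundance_weight * cc$shrunk_var),
              weighted_sq = sum(cc$abundance_weight^2 * cc$shrunk_var))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- exp(r_general + c(-1, 1) * z * sqrt(v))
  new_aggregate_trend("empirical_bayes", r_general, ci_lambda = ci,
                      variance = v, n_colonies = nrow(cc),
                      components = components)
}

#' Pool colony trends into a national growth rate
#'
#' Convenience wrapper: fits nothing itself, just routes a census collection
#' and its fitted trends through either the simple abundance-by-years
#' weighting or the empirical-Bayes shrinkage (which is restricted to
#' colonies with >= 3 records, the only ones carrying a trend variance).
#'
#' @param x a [census()] collection (colonies with >= 2 records).
#' @param trends matching list of `colony_trend` objects, e.g. from
#'   [fit_trends()].
#' @param method `"simple"` or `"eb"`.
#' @param exclude character vector of colony ids to drop first (e.g. `"IM"`
#'   to contrast totals with and without the Malvinas/Falklands unit).
#' @param ci,n_boot,level,seed passed to [aggregate_simple()] for the colony
#'   bootstrap; `level` also sets the EB interval.
#' @return an `aggregate_trend`.
#' @export
aggregate_trends <- function(x, trends, method = c("simple", "eb"),
                             exclude = NULL, ci = FALSE, n_boot = 1000,
                             level = 0.95, seed = NULL) {
  stopifnot(inherits(x, "census"))
  method <- match.arg(method)
  trends <- align_trends(trends, names(x))
  if (length(exclude)) {
    keep <- setdiff(names(x), exclude)
    x <- x[keep]
    trends <- trends[keep]
  }
  if (method == "simple") {
    aggregate_simple(trends, simple_weights(x), ci = ci, n_boot = n_boot,
                     level = level, seed = seed)
  } else {
    nr <- vapply(x, n_records, integer(1))
    keep <- names(x)[nr >= 3L]
    aggregate_eb(eb_shrink(trends[keep], x[keep]), level = level)
  }
}

#' @export
print.aggregate_trend <- function(x, ...) {
  cat(sprintf("<aggregate_trend> method: %s, %d colonies\n", x$method,
              x$n_colonies))
  cat(sprintf("  r_general = %.5f   lambda_general = %.4f\n",
              x$r_general, x$lambda_general))
  if (!is.null(x$ci_lambda)) {
    cat(sprintf("  CI for lambda: [%.4f, %.4f]\n", x$ci_lambda[1], x$ci_lambda[2]))
  }
  if (!is.na(x$variance)) cat(sprintf("  pooled variance: %.3g\n", x$variance))
  invisible(x)
}

#' @export
coef.aggregate_trend <- function(object, ...) {
  c(r_general = object$r_general, lambda_general = object$lambda_general)
}
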