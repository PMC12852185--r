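# fixtures built in code: small series and trend stubs used across tests

malvinas_series <- function() {
  colony_series("IM", c(1989, 2019), c(1300000, 100000),
                name = "Islas Malvinas", region = "Malvinas")
}

# exact exponential series: fit_log_linear recovers r with zero residuals
perfect_series <- function(r = log(1.1), n0 = 100, years = 2000:2004, id = "PF") {
  colony_series(id, years, n0 * exp(r * (years - years[1])))
}

# a trend stub with prescribed r/var_r, for aggregation oracles
trend_stub <- function(id, r, var_r = NA_real_) {
  structure(list(colony_id = id, r = r, lambda = exp(r), var_r = var_r,
                 ci_lambda = NULL, classification = classify_trend(r)),
            class = "colony_trend")
}

# expected coverage of a nominal-level percentile interval from a
# residual-based normal approximation when the truth is t with n - 2 df
t_oracle_coverage <- function(n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  2 * pt(z, df = n - 2) - 1
}
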