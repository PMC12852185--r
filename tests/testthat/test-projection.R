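test_that("Malvinas interpolation to 1996 reproduces the published figure", {
  im <- malvinas_series()
  fit <- fit_two_point(im)
  res <- interpolate_to_year(im, fit, 1996)
  expect_identical(res$status, "interpolated")
  expect_equal(res$anchor_year, 1989)
  expect_equal(res$abundance, 714535, tolerance = 0.001)
  expect_equal(res$abundance, 1300000 * fit$lambda^7, tolerance = 1e-12)
})

test_that("interpolation is anchor-consistent and guards backward extrapolation", {
  s <- colony_series("K", c(2005, 2010, 2015), c(100, 150, 190))
  fit <- fit_log_linear(s)
  for (yr in c(2005, 2010, 2015)) {
    res <- interpolate_to_year(s, fit, yr)
    expect_identical(res$status, "observed")
    expect_equal(res$abundance,
                 s$records$breeding_pairs[s$records$season_year == yr])
  }
  # inside the span: anchored at the latest census at or before the year
  mid <- interpolate_to_year(s, fit, 2012)
  expect_equal(mid$anchor_year, 2010)
  expect_equal(mid$abundance, 150 * fit$lambda^2)

  back <- interpolate_to_year(s, fit, 1996)
  expect_identical(back$status, "excluded_backward")
  expect_true(is.na(back$abundance))

  # guard off (testing only): evaluated backward from the first census
  back2 <- interpolate_to_year(s, fit, 2000, allow_backward = TRUE)
  expect_equal(back2$abundance, 100 * fit$lambda^-5)

  expect_error(interpolate_to_year(s, fit_two_point(malvinas_series()), 2010),
               "does not belong")
})

test_that("projection compounds from the most recent census", {
  im <- malvinas_series()
  fit <- fit_two_point(im)
  expect_equal(project_to_year(im, fit, 2024), 100000 * exp(fit$r * 5),
               tolerance = 1e-12)
  expect_equal(project_to_year(im, fit, 2019), 100000)  # anchor year itself
  flat <- trend_stub("IM", 0)
  expect_equal(project_to_year(im, flat, 2030), 100000)  # lambda = 1
  expect_error(project_to_year(im, fit, 2000), "precedes the last census")
})

test_that("recent-phase lambda refits only the latest records", {
  s <- colony_series("EP", c(2000, 2005, 2010, 2015), c(10, 1000, 1200, 1300))
  rec <- recent_lambda(s, window = 3)
  expect_equal(rec$r, (log(1300) - log(1000)) / 10, tolerance = 1e-12)
  expect_true(rec$recent)
  expect_identical(rec$method, "log_linear")
  # the full-series boom rate is far higher
  full <- fit_two_point(colony_series("EP", c(2000, 2015), c(10, 1300)))
  expect_equal(round(full$lambda, 3), 1.383)
  expect_gt(full$lambda, rec$lambda)

  # constant recent counts after an early boom
  s2 <- colony_series("EP", c(2000, 2010, 2012, 2014), c(10, 500, 500, 500))
  expect_equal(recent_lambda(s2, 3)$lambda, 1, tolerance = 1e-12)

  # window = series length reproduces the full fit
  expect_equal(recent_lambda(s, 4)$r, fit_log_linear(s)$r, tolerance = 1e-14)
  expect_error(recent_lambda(s, 5), "window")
  expect_error(recent_lambda(s, 1), ">= 2")
})

test_that("percent change matches the published reporting arithmetic", {
  expect_equal(percent_change(863670, 1280900, digits = 0), 48)
  expect_equal(percent_change(990393, 1280900, digits = 0), 29)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(100, 50), -50)
  expect_error(percent_change(0, 5), "undefined")
})

test_that("national summary reduces to the single-colony case", {
  im <- malvinas_series()
  cen <- census(im)
  tr <- list(IM = fit_two_point(im))
  ns <- national_summary(cen, tr, projection_config(
    recent_lambda_colonies = character(0)))
  t96 <- ns$totals[ns$totals$year == 1996, ]
  expect_equal(t96$national_incl_malvinas,
               interpolate_to_year(im, tr$IM, 1996)$abundance)
  expect_equal(t96$national_excl_malvinas, 0)
  t24 <- ns$totals[ns$totals$year == 2024, ]
  expect_equal(t24$malvinas, project_to_year(im, tr$IM, 2024))
})

test_that("national totals equal the brute-force sum of per-colony calls", {
  set.seed(5)
  series <- lapply(1:10, function(i) {
    yrs <- sort(sample(1990:2020, sample(2:5, 1)))
    simulate_colony(rnorm(1, 0, 0.05), exp(runif(1, 3, 8)), yrs, 0.1,
                    colony_id = sprintf("C%02d", i))
  })
  cen <- census(series)
  tr <- fit_trends(cen)
  cfg <- projection_config(recent_lambda_colonies = character(0),
                           malvinas_id = "C01")
  ns <- national_summary(cen, tr, cfg)
  for (yr in c(1996, 2006, 2016, 2024)) {
    brute <- vapply(names(cen), function(id) {
      last <- max(cen[[id]]$records$season_year)
      if (yr > last) project_to_year(cen[[id]], tr[[id]], yr)
      else {
        z <- interpolate_to_year(cen[[id]], tr[[id]], yr)
        if (is.na(z$abundance)) 0 else z$abundance
      }
    }, numeric(1))
    tot <- ns$totals[ns$totals$year == yr, ]
    expect_equal(tot$national_incl_malvinas, sum(brute), tolerance = 1e-9)
    # strata add up: subtotals exclude the configured Malvinas-like unit
    expect_equal(tot$two_record + tot$three_plus_record,
                 tot$national_excl_malvinas, tolerance = 1e-9)
    expect_equal(tot$national_excl_malvinas + tot$malvinas,
                 tot$national_incl_malvinas, tolerance = 1e-9)
    # internal consistency with percent_change
    if (yr > 1996) {
      t0 <- ns$totals$national_incl_malvinas[ns$totals$year == 1996]
      expect_equal(percent_change(t0, tot$national_incl_malvinas),
                   100 * (tot$national_incl_malvinas - t0) / t0)
    }
  }
})

test_that("recent-phase rates apply only from the configured year onward", {
  ep <- colony_series("EP", c(2000, 2005, 2010, 2015), c(10, 1000, 1200, 1300))
  oth <- colony_series("OT", c(1990, 2000, 2010), c(100, 110, 125))
  cen <- census(ep, oth)
  tr <- fit_trends(cen)
  ns <- national_summary(cen, tr, projection_config(malvinas_id = "none"))
  lam <- ns$colonies[ns$colonies$colony_id == "EP", c("year", "lambda_used", "recent")]
  rec <- recent_lambda(ep, 3)$lambda
  expect_equal(lam$lambda_used[lam$year == 2016], rec)
  expect_equal(lam$lambda_used[lam$year == 2024], rec)
  expect_equal(lam$lambda_used[lam$year == 2006], tr$EP$lambda)
  expect_true(all(lam$recent[lam$year >= 2016]))
})

test_that("raising one colony's growth rate cannot lower a future total", {
  a <- colony_series("A", c(2000, 2010), c(100, 150))
  b <- colony_series("B", c(2000, 2010), c(200, 180))
  cen <- census(a, b)
  tr <- fit_trends(cen)
  cfg <- projection_config(recent_lambda_colonies = character(0),
                           malvinas_id = "none")
  base <- national_summary(cen, tr, cfg)$totals
  tr$A <- trend_stub("A", tr$A$r + 0.05)
  up <- national_summary(cen, tr, cfg)$totals
  expect_true(all(up$national_incl_malvinas >= base$national_incl_malvinas - 1e-9))
})
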