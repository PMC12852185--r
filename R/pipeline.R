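#' Pipeline run configuration
#'
#' @param input path to a census CSV, or a [census()] object.
#' @param output_dir directory for the report bundle (created if absent).
#' @param seed run-level integer seed; per-stage seeds are derived from it by
#'   [derive_seed()], so adding a stage never perturbs earlier stages.
#' @param n_boot residual-bootstrap replicates per colony.
#' @param agg_boot colony-bootstrap replicates for the simple aggregate CI.
#' @param level confidence level.
#' @param exclude colony ids contrasted by exclusion in the aggregation stage
#'   (default "IM").
#' @param projection a [projection_config()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(input, output_dir, seed = 1L, n_boot = 2000,
                       agg_boot = 1000, level = 0.95, exclude = "IM",
                       projection = projection_config()) {
  structure(list(input = input, output_dir = output_dir,
                 seed = as.integer(seed), n_boot = n_boot,
                 agg_boot = agg_boot, level = level, exclude = exclude,
                 projection = projection,
                 package_version = as.character(utils::packageVersion("pentrend"))),
            class = "run_config")
}

#' Count trend classifications
#'
#' @param trends list of `colony_trend` objects.
#' @return a list with `n_increasing`, `n_declining`, `n_stable` (by sign of
#'   `r`) and the counts of the five classification labels.
#' @export
trend_tallies <- function(trends) {
  r <- vapply(trends, `[[`, numeric(1), "r")
  cls <- vapply(trends, `[[`, character(1), "classification")
  labs <- c("positive_significant", "negative_significant", "stable",
            "positive_unsupported", "negative_unsupported")
  list(n_increasing = sum(r > 0), n_declining = sum(r < 0),
       n_stable = sum(r == 0),
       classification = as.list(table(factor(cls, levels = labs))))
}

#' Run the full census-to-report pipeline
#'
#' Executes fit -> classify -> aggregate (simple and empirical-Bayes, with
#' and without the configured exclusions) -> interpolate/project -> summary,
#' writing a report bundle to `output_dir`: per-colony trend and component
#' CSVs, abundance tables, a text report with the trend tallies, the full run
#' configuration as YAML, and a log of seeds and settings. Output is
#' bit-identical for a fixed configuration and input.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages (they go to standard error).
#' @return (invisibly) a list with the in-memory results: `trends`,
#'   `tallies`, `aggregates`, `abundance`, and the output file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  cen <- if (inherits(config$input, "census")) config$input
         else read_census(config$input)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  say("fit: %d colonies", length(cen))
  trends <- fit_trends(cen, ci = TRUE, n_boot = config$n_boot,
                       level = config$level,
                       seed = derive_seed(config$seed, "fit"))
  trend_df <- summary(trends)
  write_num_csv(trend_df, out("trends.csv"))

  tallies <- trend_tallies(trends)

  say("aggregate: simple and empirical-Bayes")
  nr <- vapply(cen, n_records, integer(1))
  cen2 <- cen[nr >= 2L]
  aggregates <- list()
  variants <- list(all = NULL)
  excl <- intersect(config$exclude, names(cen2))
  if (length(excl)) variants$excluded <- excl
  for (v in names(variants)) {
    aggregates[[paste0("simple_", v)]] <-
      aggregate_trends(cen2, trends, method = "simple", exclude = variants[[v]],
                       ci = TRUE, n_boot = config$agg_boot, level = config$level,
                       seed = derive_seed(config$seed, paste0("aggregate_", v)))
    has3 <- sum(nr[setdiff(names(cen2), variants[[v]])] >= 3L)
    if (has3 >= 2L) {
      aggregates[[paste0("eb_", v)]] <-
        aggregate_trends(cen2, trends, method = "eb", exclude = variants[[v]],
                         level = config$level)
    }
  }
  agg_df <- do.call(rbind, lapply(names(aggregates), function(nm) {
    a <- aggregates[[nm]]
    data.frame(variant = nm, method = a$method, n_colonies = a$n_colonies,
               r_general = a$r_general, lambda_general = a$lambda_general,
               ci_low = if (is.null(a$ci_lambda)) NA_real_ else a$ci_lambda[1],
               ci_high = if (is.null(a$ci_lambda)) NA_real_ else a$ci_lambda[2],
               stringsAsFactors = FALSE)
  }))
  write_num_csv(agg_df, out("aggregates.csv"))

  say("project: years %s + %d",
      paste(config$projection$reference_years, collapse = ", "),
      config$projection$projection_year)
  abund <- national_summary(cen2, trends, config$projection)
  write_num_csv(abund$colonies, out("abundance_colonies.csv"))
  write_num_csv(abund$totals, out("abundance_totals.csv"))

  rep_lines <- c(
    "pentrend pipeline report",
    sprintf("colonies analyzed: %d (of %d; %d single-record excluded)",
            length(cen2), length(cen), sum(nr < 2L)),
    sprintf("increasing: %d  declining: %d  stable: %d",
            tallies$n_increasing, tallies$n_declining, tallies$n_stable),
    sprintf("significant positive: %d  significant negative: %d  stable (CI): %d",
            tallies$classification$positive_significant,
            tallies$classification$negative_significant,
            tallies$classification$stable),
    vapply(names(aggregates), function(nm) {
      a <- aggregates[[nm]]
      sprintf("%s: lambda_general = %.4f%s", nm, a$lambda_general,
              if (is.null(a$ci_lambda)) "" else
                sprintf(" [%.4f, %.4f]", a$ci_lambda[1], a$ci_lambda[2]))
    }, character(1)),
    vapply(seq_len(nrow(abund$totals)), function(i) {
      sprintf("%d: national total %.0f (excl. Malvinas unit %.0f)",
              abund$totals$year[i], abund$totals$national_incl_malvinas[i],
              abund$totals$national_excl_malvinas[i])
    }, character(1)))
  writeLines(rep_lines, out("report.txt"))

  cfg <- unclass(config)
  cfg$input <- if (inherits(config$input, "census")) "<in-memory census>" else config$input
  cfg$projection <- unclass(cfg$projection)
  yaml::write_yaml(cfg, out("run_config.yaml"))
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("stage seed fit: %d", derive_seed(config$seed, "fit")),
               sprintf("stage seed aggregate_all: %d",
                       derive_seed(config$seed, "aggregate_all")),
               sprintf("n_boot: %d  agg_boot: %d  level: %g",
                       config$n_boot, config$agg_boot, config$level)),
             out("run.log"))

  invisible(list(trends = trends, tallies = tallies, aggregates = aggregates,
                 abundance = abund,
                 files = list.files(config$output_dir, full.names = TRUE)))
}

# CSV writer with full-precision numerics, for bit-identical reruns
write_num_csv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(z) sprintf("%.17g", z))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Recompute the in-source worked results
#'
#' Recomputes, from the printed inputs bundled with the package, the worked
#' quantities that can be checked against the published study without the
#' undeposited per-colony census series: the Malvinas/Falklands two-point
#' fit, its 1996 interpolation and 2024 projection, the trend tallies and
#' internal consistency of the published table, and the percent-change
#' arithmetic on the published national totals.
#'
#' @return a named list of the recomputed values.
#' @export
reproduce_published <- function() {
  im <- colony_series("IM", c(1989, 2019), c(1300000, 100000),
                      name = "Islas Malvinas", region = "Malvinas")
  fit <- fit_two_point(im)
  n1996 <- interpolate_to_year(im, fit, 1996)$abundance
  n2024 <- project_to_year(im, fit, 2024)
  t1 <- load_table1()
  list(
    im_lambda = fit$lambda,
    im_r = fit$r,
    im_1996 = n1996,
    im_2024 = n2024,
    im_decline_pct = 100 * (1 - n2024 / n1996),
    table1_max_lambda_gap = max(abs(t1$lambda - exp(t1$r))),
    n_increasing = sum(t1$r > 0),
    n_declining = sum(t1$r < 0),
    pct_1996_2024 = percent_change(863670, 1280900),
    pct_2016_2024 = percent_change(990393, 1280900),
    pct_three_plus = percent_change(599320, 1087281),
    im_contribution_2024 = 1348100 - 1280900)
}
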