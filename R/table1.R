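#' Load the published per-colony trend table
#'
#' Returns the transcription of the published table of 65 Magellanic penguin
#' colonies analyzed along the Argentine coast: colony code, name, printed
#' coordinates (also parsed to decimal degrees, south/west negative), region,
#' the printed instantaneous growth rate `r`, finite growth rate `lambda`,
#' the 95% bootstrap confidence interval where one was printed (colonies with
#' three or more census records), and the printed significance flag. These are
#' the published values, kept verbatim for validation; the package's fitting
#' functions do not read them.
#'
#' @return a data frame with 65 rows and columns `row`, `colony_id`, `name`,
#'   `coords`, `latitude`, `longitude`, `region`, `r`, `lambda`, `ci_low`,
#'   `ci_high`, `significant`.
#' @examples
#' t1 <- load_table1()
#' table(sign(t1$r))   # 33 increasing, 32 declining colonies
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_trends.csv", package = "pentrend",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df$significant <- as.logical(df$significant)
  ll <- parse_coords(df$coords)
  df$latitude <- ll$latitude
  df$longitude <- ll$longitude
  df[, c("row", "colony_id", "name", "coords", "latitude", "longitude",
         "region", "r", "lambda", "ci_low", "ci_high", "significant")]
}
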