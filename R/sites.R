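#' Collection-site characteristics
#'
#' Water-quality measurements taken at the eight New Zealand collection
#' sites at the time of fish collection (January 2016). Four sites have
#' geothermal influence ("warm" source), four follow air temperature
#' ("ambient" source). Temperatures are spot measurements in degrees
#' Celsius; the annual range comes from bi-monthly readings over one year.
#'
#' @return a tibble with columns `source`, `site`, `collection_temp_C`,
#'   `annual_min_C`, `annual_max_C`, `conductivity_uScm`, `pH`, `DO_pct`.
#' @examples
#' collection_sites()
#' @export
collection_sites <- function() {
  tibble::tibble(
    source = rep(c("ambient", "warm"), each = 4L),
    site = c(
      "Twilight Stream", "Tahnua Torea", "Tourist Stream", "Auckland Domain",
      "Lake Ohakuri", "Miranda Hot Spring", "Awakeri Spring", "Akatarewa Stream"
    ),
    collection_temp_C = c(19.6, 21.3, 21.8, 24.8, 30.0, 32.1, 35.1, 36.0),
    annual_min_C = c(13, 12, 13, 12, 26, 29, 35, 24),
    annual_max_C = c(20, 23, 23, 25, 30, 35, 37, 37),
    conductivity_uScm = c(140, 275, 134, 307, 337, 632, 889, 483),
    pH = c(7.03, 7.55, 6.99, 7.64, 7.51, 7.88, 7.52, 7.43),
    DO_pct = c(66, 82.2, 51, 55.5, 104, 141.7, 63.3, 75.5)
  )
}

#' Warm-minus-ambient collection temperature contrast
#'
#' Mean collection temperature of warm-source sites minus that of
#' ambient-source sites.
#'
#' @param sites site table as returned by [collection_sites()].
#' @param digits rounding applied to the contrast; use `digits = 0` for the
#'   whole-degree summary.
#' @return the temperature contrast in degrees Celsius.
#' @examples
#' collection_temp_contrast(digits = 0)
#' @export
collection_temp_contrast <- function(sites = collection_sites(), digits = NULL) {
  stopifnot(all(c("source", "collection_temp_C") %in% names(sites)))
  m <- tapply(sites$collection_temp_C, sites$source, mean)
  if (!all(c("warm", "ambient") %in% names(m))) {
    stop("`sites` must contain both 'warm' and 'ambient' sources")
  }
  out <- unname(m[["warm"]] - m[["ambient"]])
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Generations elapsed since introduction
#'
#' Number of generations between two calendar years assuming a fixed number
#' of generations per year. Mosquitofish reached New Zealand in the early
#' 1930s and breed roughly twice a year, giving ~170 generations by the
#' 2016 collections.
#'
#' @param start_year,end_year calendar years.
#' @param generations_per_year generations completed per year.
#' @return number of generations (numeric).
#' @examples
#' generations_elapsed(1931, 2016, 2)
#' @export
generations_elapsed <- function(start_year = 1931, end_year = 2016,
                                generations_per_year = 2) {
  if (end_year < start_year) stop("`end_year` must be >= `start_year`")
  (end_year - start_year) * generations_per_year
}
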