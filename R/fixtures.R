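fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "stentmra")
  if (p == "") abort(paste0("packaged fixture not found: ", file))
  p
}

#' The 22-stent catalogue
#'
#' Transcription of the published stent table: 21 peripheral arterial stents
#' and one stentgraft (10 nitinol, 7 316L steel, 2 tantalum, 1 cobalt
#' superalloy, 1 PET-covered cobalt superalloy, 1 platinum alloy), with
#' manufacturer, nominal diameter (5-13 mm) and length.
#'
#' @return A tibble with columns `stent_id`, `name`, `manufacturer`,
#'   `material`, `primary_use`, `diameter_mm`, `length_mm`.
#' @export
stent_table1 <- function() {
  readr::read_csv(fixture_path("stents_table1.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Published in vitro lumen-visibility measurements
#'
#' Transcription of the bench measurement table for all 22 stents imaged at
#' 1.5 T: relative in-stent signal intensity (percent of the unstented
#' reference), minimal visible lumen diameter (percent), and lumen SD/mean
#' homogeneity, together with the per-category scores as printed
#' (`*_printed` columns). Two printed values are internally inconsistent
#' with the stated rules and are preserved verbatim: stent 7 (visible lumen
#' 38% printed with score 2) and, in [overall_table3()], stent 10 (overall
#' score 7 printed as class good).
#'
#' @return A tibble with columns `stent_id`, `name`, `si_percent`,
#'   `score_si_printed`, `vis_min_percent`, `score_vis_printed`,
#'   `sd_over_mean`, `score_hom_printed`.
#' @export
measurements_table2 <- function() {
  readr::read_csv(fixture_path("measurements_table2.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Published overall grading of the 22 stents
#'
#' The printed per-category scores, overall score (3-9) and overall class
#' for each stent.
#'
#' @return A tibble with columns `stent_id`, `name`, `score_si`,
#'   `score_vis`, `score_hom`, `overall_score`, `overall_class`.
#' @export
overall_table3 <- function() {
  readr::read_csv(fixture_path("overall_table3.csv"),
                  show_col_types = FALSE, progress = FALSE)
}
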