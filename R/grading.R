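#' Grading thresholds for the three-category score
#'
#' The published cut-offs: relative signal intensity — poor below 40%, good
#' above 60%, intermediate in between (boundaries inclusive in the
#' intermediate band); minimal visible lumen diameter — poor below 40%, good
#' above 70%; homogeneity SD/mean — poor at or above 0.4, good below 0.1.
#' Category scores (1/2/3) are summed to an overall score of 3-9, classified
#' poor (3-4), intermediate (5-7) or good (8-9).
#'
#' @param si_poor_below,si_good_above Signal-intensity cut-offs, percent.
#' @param vis_poor_below,vis_good_above Visible-lumen cut-offs, percent.
#' @param hom_poor_at_or_above,hom_good_below Homogeneity cut-offs, ratio.
#' @param overall_poor_max,overall_good_min Overall-score cut-offs.
#' @return A `grading_thresholds` list.
#' @export
grading_thresholds <- function(si_poor_below = 40, si_good_above = 60,
                               vis_poor_below = 40, vis_good_above = 70,
                               hom_poor_at_or_above = 0.4, hom_good_below = 0.1,
                               overall_poor_max = 4, overall_good_min = 8) {
  stopifnot(si_poor_below < si_good_above,
            vis_poor_below < vis_good_above,
            hom_good_below < hom_poor_at_or_above,
            overall_poor_max < overall_good_min)
  structure(list(si_poor_below = si_poor_below, si_good_above = si_good_above,
                 vis_poor_below = vis_poor_below, vis_good_above = vis_good_above,
                 hom_poor_at_or_above = hom_poor_at_or_above,
                 hom_good_below = hom_good_below,
                 overall_poor_max = overall_poor_max,
                 overall_good_min = overall_good_min),
            class = "grading_thresholds")
}

grade_levels <- c("poor", "intermediate", "good")

#' Grade relative signal intensity
#'
#' 1 (poor) below 40%, 2 (intermediate) for 40-60% inclusive, 3 (good)
#' above 60%.
#'
#' @param si_percent Relative signal intensity, percent (>= 0). Vectorised.
#' @param thresholds A [grading_thresholds()].
#' @return Integer scores in 1:3.
#' @export
grade_signal_intensity <- function(si_percent, thresholds = grading_thresholds()) {
  if (any(si_percent < 0, na.rm = TRUE)) abort("si_percent must be >= 0")
  ifelse(si_percent < thresholds$si_poor_below, 1L,
         ifelse(si_percent > thresholds$si_good_above, 3L, 2L))
}

#' Grade lumen narrowing
#'
#' Scored on the minimal visible lumen diameter: 1 below 40%, 2 for 40-70%
#' inclusive, 3 above 70%. Values above 100% are clamped with a warning.
#'
#' @param vis_min_percent Minimal visible lumen diameter, percent.
#' @inheritParams grade_signal_intensity
#' @return Integer scores in 1:3.
#' @export
grade_lumen_narrowing <- function(vis_min_percent, thresholds = grading_thresholds()) {
  if (any(vis_min_percent < 0, na.rm = TRUE)) abort("vis_min_percent must be >= 0")
  if (any(vis_min_percent > 100, na.rm = TRUE)) {
    warn("vis_min_percent above 100 clamped to 100")
    vis_min_percent <- pmin(vis_min_percent, 100)
  }
  ifelse(vis_min_percent < thresholds$vis_poor_below, 1L,
         ifelse(vis_min_percent > thresholds$vis_good_above, 3L, 2L))
}

#' Grade lumen homogeneity
#'
#' 1 (poor) at or above 0.4, 2 (intermediate) in [0.1, 0.4), 3 (good) below
#' 0.1. A printed SD/mean of exactly 0.10 therefore scores 2.
#'
#' @param sd_over_mean Homogeneity ratio (>= 0). Vectorised.
#' @inheritParams grade_signal_intensity
#' @return Integer scores in 1:3.
#' @export
grade_homogeneity <- function(sd_over_mean, thresholds = grading_thresholds()) {
  if (any(sd_over_mean < 0, na.rm = TRUE)) abort("sd_over_mean must be >= 0")
  ifelse(sd_over_mean >= thresholds$hom_poor_at_or_above, 1L,
         ifelse(sd_over_mean < thresholds$hom_good_below, 3L, 2L))
}

#' Overall score and class from the three category scores
#'
#' @param score_si,score_vis,score_hom Category scores in 1:3 (vectorised).
#' @inheritParams grade_signal_intensity
#' @return A tibble with columns `overall_score` (3-9) and `overall_class`
#'   (ordered factor poor < intermediate < good).
#' @export
overall_grade <- function(score_si, score_vis, score_hom,
                          thresholds = grading_thresholds()) {
  sc <- cbind(score_si, score_vis, score_hom)
  if (any(!sc %in% 1:3)) abort("category scores must be 1, 2 or 3")
  total <- score_si + score_vis + score_hom
  cls <- ifelse(total <= thresholds$overall_poor_max, "poor",
                ifelse(total >= thresholds$overall_good_min, "good",
                       "intermediate"))
  tibble(overall_score = as.integer(total),
         overall_class = factor(cls, levels = grade_levels, ordered = TRUE))
}

#' Grade a table of measurements
#'
#' Data-frame-first grading: applies the three category rules and the
#' overall classification to every row of a measurement table. Grading
#' operates on the reported precision (integer percents, two-decimal
#' homogeneity), so regrading a printed measurement table is exact.
#'
#' @param measurements A data frame with columns `si_percent`,
#'   `vis_min_percent`, `sd_over_mean` and ideally `stent_id`/`name` (e.g.
#'   from [measurements_table2()] or [measure_phantom()]).
#' @param thresholds A [grading_thresholds()].
#' @return A `stent_grades` tibble: the input id columns plus `score_si`,
#'   `score_vis`, `score_hom`, `overall_score`, `overall_class`, ordered by
#'   `stent_id`.
#' @examples
#' grade_measurements(measurements_table2())
#' @export
grade_measurements <- function(measurements, thresholds = grading_thresholds()) {
  need <- c("si_percent", "vis_min_percent", "sd_over_mean")
  missing <- setdiff(need, names(measurements))
  if (length(missing)) {
    abort(paste0("measurements lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(measurements$stent_id %||% integer())) {
    abort("stent_id values must be unique")
  }
  out <- tibble::as_tibble(measurements) |>
    dplyr::mutate(
      si_percent = round(.data$si_percent),
      vis_min_percent = round(.data$vis_min_percent),
      sd_over_mean = round(.data$sd_over_mean, 2),
      score_si = grade_signal_intensity(.data$si_percent, thresholds),
      score_vis = grade_lumen_narrowing(.data$vis_min_percent, thresholds),
      score_hom = grade_homogeneity(.data$sd_over_mean, thresholds))
  out <- dplyr::bind_cols(
    out, overall_grade(out$score_si, out$score_vis, out$score_hom, thresholds))
  if ("stent_id" %in% names(out)) out <- dplyr::arrange(out, .data$stent_id)
  structure(out, thresholds = thresholds,
            class = c("stent_grades", class(out)))
}

#' Category and overall class tallies
#'
#' Counts stents per class (good/intermediate/poor) for each of the three
#' categories and for the overall classification — the group sizes quoted in
#' comparative visibility studies.
#'
#' @param grades A `stent_grades` table from [grade_measurements()].
#' @return A tibble with columns `category` (si, vis, hom, overall) and
#'   `good`, `intermediate`, `poor` counts.
#' @export
grade_counts <- function(grades) {
  count3 <- function(score) {
    c(good = sum(score == 3L), intermediate = sum(score == 2L),
      poor = sum(score == 1L))
  }
  rows <- list(
    si = count3(grades$score_si),
    vis = count3(grades$score_vis),
    hom = count3(grades$score_hom),
    overall = c(good = sum(grades$overall_class == "good"),
                intermediate = sum(grades$overall_class == "intermediate"),
                poor = sum(grades$overall_class == "poor")))
  purrr::imap(rows, \(x, nm) tibble(category = nm, !!!as.list(x))) |>
    purrr::list_rbind()
}

#' @export
print.stent_grades <- function(x, ...) {
  cat(sprintf("<stent_grades> %d stents (%s)\n", nrow(x),
              paste(levels(x$overall_class), table(x$overall_class),
                    sep = ": ", collapse = ", ")))
  NextMethod()
}

#' @rdname grade_measurements
#' @param x A `stent_grades` object.
#' @param ... Unused.
#' @export
tidy.stent_grades <- function(x, ...) {
  class(x) <- setdiff(class(x), "stent_grades")
  attr(x, "thresholds") <- NULL
  tibble::as_tibble(x)
}

#' @rdname grade_measurements
#' @export
glance.stent_grades <- function(x, ...) {
  tibble(n_stents = nrow(x),
         n_good = sum(x$overall_class == "good"),
         n_intermediate = sum(x$overall_class == "intermediate"),
         n_poor = sum(x$overall_class == "poor"),
         min_si = min(x$si_percent), max_si = max(x$si_percent),
         n_truncated = sum(x$vis_min_percent == 0))
}
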