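#' Published reference tables for the Lee-index life-expectancy calculator
#'
#' Small built-in tables reproduced from the published development of the
#' calculator in the Health and Retirement Study (HRS, 1998 wave) and the
#' English Longitudinal Study of Ageing (ELSA, 2004 wave):
#'
#' * `lee_item_points()` — the 12 Lee-index items with their point values
#'   (age bands 0/1/2/3/4/5/7; male 2; diabetes 1; cancer 2; lung disease 2;
#'   heart failure 2; BMI < 25 1; current smoker 2; difficulty bathing 2;
#'   difficulty managing finances 2; difficulty walking several blocks 2;
#'   difficulty pushing/pulling heavy objects 1) and, for the synthetic
#'   factor-level cohort mode, the per-cohort item prevalences.
#' * `cohort_group_counts()` — the number of subjects in each of the 15
#'   point-score groups (0, 1, ..., 13, 14+) for the HRS development
#'   (n = 11701), HRS validation (n = 8009) and ELSA validation (n = 7042)
#'   cohorts.
#' * `published_le_quantiles()` — the published Gompertz-predicted time to
#'   25% mortality, median life expectancy and time to 75% mortality (years)
#'   for each point group, fitted to the HRS development cohort. This is the
#'   natural input to [reconstruct_gompertz()].
#'
#' @param cohort One of `"development"`, `"validation"`, `"elsa"`.
#' @return A tibble; see Details.
#' @seealso [score_profiles()], [reconstruct_gompertz()], [hrs_cohort_spec()]
#' @examples
#' published_le_quantiles()
#' cohort_group_counts("development")
#' @name reference_tables
NULL

group_levels <- function() c(as.character(0:13), "14+")

as_group_factor <- function(x) {
  x <- as.character(x)
  x[x %in% c("14", "15", "16", ">=14", "14plus")] <- "14+"
  bad <- !x %in% group_levels()
  if (any(bad)) {
    stop("unknown risk group label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = group_levels())
}

#' @rdname reference_tables
#' @export
lee_item_points <- function() {
  tibble::tribble(
    ~item,                    ~points, ~prev_development, ~prev_validation, ~prev_elsa,
    "male",                   2L,      5062,              3493,             3173,
    "diabetes",               1L,      1608,              1246,             541,
    "cancer",                 2L,      1349,              862,              536,
    "lung_disease",           2L,      443,               376,              445,
    "heart_failure",          2L,      298,               240,              1360,
    "bmi_under_25",           1L,      4402,              2981,             1954,
    "current_smoker",         2L,      1813,              1416,             1019,
    "difficulty_bathing",     2L,      754,               644,              706,
    "difficulty_finances",    2L,      887,               737,              145,
    "difficulty_walking_blocks", 2L,   3167,              2542,             722,
    "difficulty_push_pull",   1L,      3329,              2604,             1171
  )
}

# age bands as printed: 50-59 -> 0, 60-64 -> 1, 65-69 -> 2, 70-74 -> 3,
# 75-79 -> 4, 80-84 -> 5, >=85 -> 7 (there is no 6-point band)
age_band_points <- function() {
  tibble::tibble(
    lower = c(50, 60, 65, 70, 75, 80, 85),
    upper = c(59, 64, 69, 74, 79, 84, Inf),
    points = c(0L, 1L, 2L, 3L, 4L, 5L, 7L),
    prev_development = c(3154, 2145, 1798, 1669, 1362, 856, 715),
    prev_validation = c(2328, 1547, 1188, 1017, 909, 533, 487),
    prev_elsa = c(2197, 1215, 1198, 971, 732, 481, 248)
  )
}

#' @rdname reference_tables
#' @export
cohort_group_counts <- function(cohort = c("development", "validation", "elsa")) {
  cohort <- match.arg(cohort)
  counts <- switch(cohort,
    development = c(742, 1368, 1480, 1448, 1334, 1168, 890, 762, 552, 409,
                    324, 244, 177, 315, 488),
    validation  = c(494, 889, 973, 994, 845, 762, 638, 501, 404, 310,
                    233, 192, 159, 260, 355),
    elsa        = c(459, 503, 1013, 937, 868, 810, 589, 517, 405, 296,
                    202, 154, 118, 67, 104)
  )
  tibble::tibble(group = as_group_factor(group_levels()),
                 count = as.integer(counts))
}

#' @rdname reference_tables
#' @export
published_le_quantiles <- function() {
  tibble::tibble(
    group = as_group_factor(group_levels()),
    t25 = c(27.8, 25.5, 22.7, 16.7, 14.4, 11.4, 8.7, 7.4, 5.8, 4.7, 3.8,
            2.9, 2.6, 2.3, 1.6),
    t50 = c(35.4, 33.1, 30.1, 23.7, 21.1, 17.7, 14.3, 12.6, 10.3, 8.8, 7.3,
            5.9, 5.3, 4.8, 3.4),
    t75 = c(41.5, 39.1, 36.1, 29.5, 26.8, 23.2, 19.6, 17.6, 14.9, 13.1, 11.2,
            9.4, 8.6, 7.8, 5.9)
  )
}
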