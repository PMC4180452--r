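#' Score risk-factor profiles into Lee points and risk groups
#'
#' Sums the 12 Lee-index items into a mortality point score (0–26) and the
#' 15-level risk group used throughout the package: groups 0–13 and a top
#' group `"14+"` that pools every score of 14 or more. Each row of `data` is
#' one person. Expected columns (renameable via `cols`):
#'
#' * `age_years` — integer age, 50 or over. Mapped internally to the point
#'   bands 50–59 (0), 60–64 (1), 65–69 (2), 70–74 (3), 75–79 (4), 80–84 (5),
#'   85+ (7).
#' * `male` — logical (or 0/1).
#' * `diabetes`, `cancer`, `lung_disease`, `heart_failure`, `current_smoker`
#'   — logical comorbidity/behaviour flags.
#' * `bmi_under_25` — logical; alternatively supply a numeric `bmi` column
#'   and the flag is derived as `bmi < 25` (strict).
#' * `difficulty_bathing`, `difficulty_finances`,
#'   `difficulty_walking_blocks`, `difficulty_push_pull` — logical
#'   functional-limitation flags.
#'
#' @param data A data frame, one row per person.
#' @param cols Optional named character vector mapping the expected item
#'   names above to the column names actually present, e.g.
#'   `c(age_years = "age", male = "sex_male")`.
#' @param missing How to treat `NA` item values: `"error"` (default) refuses
#'   them; `"absent"` scores them as risk-factor-absent and warns once.
#'   Missing handling in the source cohorts is not documented, so the
#'   conservative default is to refuse.
#' @return `data` as a tibble with integer `points` and factor `group`
#'   (levels `"0"` ... `"13"`, `"14+"`) columns appended.
#' @examples
#' score_profiles(data.frame(
#'   age_years = 77, male = TRUE, diabetes = FALSE, cancer = FALSE,
#'   lung_disease = FALSE, heart_failure = TRUE, bmi_under_25 = FALSE,
#'   current_smoker = FALSE, difficulty_bathing = FALSE,
#'   difficulty_finances = FALSE, difficulty_walking_blocks = TRUE,
#'   difficulty_push_pull = FALSE
#' ))  # 4 + 2 + 2 + 2 = 10 points, group 10
#' @export
score_profiles <- function(data, cols = NULL, missing = c("error", "absent")) {
  missing <- match.arg(missing)
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  flags <- lee_item_points()$item

  if (!is.null(cols)) {
    bad <- setdiff(names(cols), c("age_years", "bmi", flags))
    if (length(bad) > 0) {
      stop("`cols` maps unknown item(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    work <- data
    for (item in names(cols)) {
      if (!cols[[item]] %in% names(data)) {
        stop("mapped column `", cols[[item]], "` not found in `data`.",
             call. = FALSE)
      }
      work[[item]] <- data[[cols[[item]]]]
    }
  } else {
    work <- data
  }

  if (!"bmi_under_25" %in% names(work) && "bmi" %in% names(work)) {
    work$bmi_under_25 <- work$bmi < 25
  }
  needed <- c("age_years", flags)
  absent <- setdiff(needed, names(work))
  if (length(absent) > 0) {
    stop("missing item column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  age <- work$age_years
  item_mat <- vapply(flags, function(f) as.logical(work[[f]]),
                     logical(nrow(work)))
  item_mat <- matrix(item_mat, nrow = nrow(work),
                     dimnames = list(NULL, flags))

  any_na <- is.na(age) | rowSums(is.na(item_mat)) > 0
  if (any(any_na)) {
    if (missing == "error") {
      stop(sum(any_na), " profile(s) have missing items; set ",
           '`missing = "absent"` to score NA items as absent.', call. = FALSE)
    }
    warning(sum(any_na), " profile(s) had missing items scored as absent.",
            call. = FALSE)
    item_mat[is.na(item_mat)] <- FALSE
    if (any(is.na(age))) {
      stop("`age_years` itself may not be missing.", call. = FALSE)
    }
  }
  if (any(age < 50)) {
    stop("`age_years` must be 50 or over for every profile.", call. = FALSE)
  }

  bands <- age_band_points()
  age_pts <- bands$points[findInterval(age, bands$lower)]
  item_pts <- as.integer(item_mat %*% lee_item_points()$points)
  points <- as.integer(age_pts) + item_pts

  data$points <- points
  data$group <- as_group_factor(pmin(points, 14L))
  data
}
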