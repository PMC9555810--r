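# Bundled summary tables from a published telenursing demand study of
# empty-nest elderly individuals with chronic diseases (N = 348, surveyed in
# Yangzhou and Nantong, Jiangsu Province). The raw respondent-level data
# were not deposited; these category-count tables are sufficient to
# reproduce every derived statistic, and reconstruct_kano_survey() turns
# them back into respondent-level datasets. The same tables are shipped as
# CSV files under inst/extdata/.

telenursing_labels <- c(
  "Remote education on home safety prevention",
  "Teletraining on care skills",
  "Remote lectures about disease prevention",
  "Remote screening for diseases",
  "Distance intervention for disease risk factors",
  "Remote monitoring of vital signs and sleep",
  "Remote diagnosis of diseases",
  "Remote health counseling",
  "Remote calls for life needs",
  "Remote calls for nursing needs",
  "Remote one-button emergency caller",
  "Remote emergency assistance arrangement",
  "Remote rehabilitation guidance",
  "Remote return visits and related health education",
  "Regular family visits"
)

# attribute, m, o, a, i, q, r
telenursing_count_rows <- matrix(c(
  1, 8, 34, 170, 122, 7, 7,
  2, 4, 33, 174, 128, 6, 3,
  3, 4, 36, 170, 117, 8, 13,
  4, 11, 37, 165, 126, 5, 4,
  5, 11, 36, 169, 121, 6, 5,
  6, 105, 88, 73, 73, 7, 2,
  7, 6, 166, 82, 81, 4, 9,
  8, 7, 193, 84, 59, 4, 1,
  9, 5, 40, 120, 172, 5, 6,
  10, 5, 39, 123, 170, 8, 3,
  11, 167, 48, 72, 53, 5, 3,
  12, 153, 64, 63, 63, 4, 1,
  13, 6, 201, 82, 48, 4, 7,
  14, 7, 194, 88, 54, 3, 2,
  15, 7, 196, 88, 49, 4, 4
), ncol = 7, byrow = TRUE)

# published derived columns: final category and the four coefficients (%)
telenursing_published <- data.frame(
  attribute_id = 1:15,
  final_category = c("A", "A", "A", "A", "A", "M", "O", "O", "I", "I", "M", "M", "O", "O", "O"),
  category_strength = c(13.79, 13.22, 15.23, 11.21, 13.79, 4.89, 24.14, 31.32, 14.94, 13.51, 27.30, 25.57, 34.20, 30.46, 31.03),
  total_strength = c(60.92, 60.63, 60.34, 61.21, 62.07, 76.44, 72.99, 81.61, 47.41, 47.99, 82.47, 80.46, 83.05, 83.05, 83.62),
  better = c(61.08, 61.06, 63.00, 59.59, 60.83, 47.49, 74.03, 80.76, 47.48, 48.07, 35.29, 37.03, 83.98, 82.22, 83.53),
  worse = c(12.57, 10.91, 12.23, 14.16, 13.95, 56.93, 51.34, 58.31, 13.35, 13.06, 63.24, 63.27, 61.42, 58.60, 59.71)
)

# attribute, group A counts, group B counts, published |Z| and p
telenursing_city_rows <- matrix(c(
  1, 3, 13, 88, 59, 6, 4, 5, 21, 82, 63, 1, 3, 1.07, 0.28,
  2, 2, 16, 84, 66, 3, 2, 2, 17, 90, 62, 3, 1, 0.60, 0.55,
  3, 0, 18, 88, 57, 4, 6, 4, 18, 82, 60, 4, 7, 0.03, 0.97,
  4, 4, 18, 82, 63, 3, 3, 7, 19, 83, 63, 2, 1, 0.70, 0.49,
  5, 3, 20, 86, 58, 3, 3, 8, 16, 83, 63, 3, 2, 0.12, 0.91,
  6, 50, 49, 33, 35, 4, 2, 55, 39, 40, 38, 3, 0, 0.05, 0.96,
  7, 1, 91, 39, 37, 0, 5, 5, 75, 43, 44, 4, 4, 1.24, 0.22,
  8, 2, 102, 43, 25, 0, 1, 5, 91, 41, 34, 4, 0, 1.12, 0.26,
  9, 1, 19, 52, 96, 1, 4, 4, 21, 68, 76, 4, 2, 1.92, 0.054,
  10, 2, 20, 58, 87, 4, 2, 3, 19, 65, 83, 4, 1, 0.57, 0.57,
  11, 80, 22, 45, 23, 2, 1, 87, 26, 27, 30, 3, 2, 0.36, 0.72,
  12, 81, 30, 31, 28, 2, 1, 72, 34, 32, 35, 2, 0, 1.00, 0.32,
  13, 1, 104, 40, 22, 2, 4, 5, 97, 42, 26, 2, 3, 0.19, 0.85,
  14, 3, 94, 45, 28, 1, 2, 4, 100, 43, 26, 2, 0, 0.71, 0.48,
  15, 1, 96, 48, 24, 2, 2, 6, 100, 40, 25, 2, 2, 0.94, 0.35
), ncol = 15, byrow = TRUE)

telenursing_residence_rows <- matrix(c(
  1, 4, 16, 81, 65, 4, 3, 4, 18, 89, 57, 3, 4, 0.85, 0.40,
  2, 2, 14, 81, 71, 2, 3, 2, 19, 93, 57, 4, 0, 1.74, 0.08,
  3, 2, 16, 83, 60, 4, 8, 2, 20, 87, 57, 4, 5, 0.92, 0.36,
  4, 4, 17, 83, 64, 2, 3, 7, 20, 82, 62, 3, 1, 0.74, 0.46,
  5, 5, 18, 83, 61, 2, 4, 6, 18, 86, 60, 4, 1, 0.34, 0.74,
  6, 53, 40, 35, 40, 3, 2, 52, 48, 38, 33, 4, 0, 0.54, 0.59,
  7, 2, 84, 39, 40, 3, 5, 4, 82, 43, 41, 1, 4, 0.22, 0.82,
  8, 4, 92, 44, 31, 1, 1, 3, 101, 40, 28, 3, 0, 0.58, 0.56,
  9, 2, 17, 66, 81, 4, 3, 3, 23, 54, 91, 1, 3, 0.02, 0.98,
  10, 3, 19, 64, 82, 3, 2, 2, 20, 59, 88, 5, 1, 0.58, 0.56,
  11, 79, 23, 39, 27, 3, 2, 88, 25, 33, 26, 2, 1, 0.98, 0.33,
  12, 75, 30, 34, 32, 1, 1, 78, 34, 29, 31, 3, 0, 0.33, 0.74,
  13, 3, 93, 46, 26, 2, 3, 3, 108, 36, 22, 2, 4, 1.28, 0.20,
  14, 3, 94, 45, 26, 3, 2, 4, 100, 43, 28, 0, 0, 0.78, 0.44,
  15, 4, 93, 45, 28, 2, 1, 3, 103, 43, 21, 2, 3, 0.78, 0.44
), ncol = 15, byrow = TRUE)

telenursing_demo_rows <- data.frame(
  covariate = rep(
    c("gender", "age_band", "education", "residence_city", "living_condition"),
    times = c(2, 3, 5, 4, 2)
  ),
  level = c(
    "Female", "Male",
    "65-74", "75-84", "85 and above",
    "Illiterate or barely literate", "Primary school", "Junior high school",
    "Senior high school or technical secondary school",
    "Junior college diploma or higher",
    "Urban (Yangzhou)", "Urban (Nantong)", "Rural (Yangzhou)", "Rural (Nantong)",
    "Living alone", "With spouse"
  ),
  n = c(196, 152, 221, 113, 14, 78, 97, 92, 44, 37, 87, 88, 86, 87, 155, 193),
  pct = c(
    56.32, 43.68, 63.51, 32.47, 4.02, 22.41, 27.87, 26.44, 12.64, 10.63,
    25.00, 25.29, 24.71, 25.00, 44.54, 55.46
  )
)

#' Catalogue of the 15 telenursing service attributes
#'
#' Short labels for the fifteen telenursing services evaluated in the
#' bundled study, in questionnaire order.
#'
#' @return A tibble with `attribute_id` (1-15) and `label`.
#' @export
telenursing_attributes <- function() {
  tibble::tibble(attribute_id = 1:15, label = telenursing_labels)
}

#' Per-attribute Kano category counts from the telenursing study
#'
#' Category tallies (M, O, A, I, Q, R) for each of the 15 attributes over
#' the 348 valid respondents. Internal consistency (every row sums to 348)
#' is re-checked on every call.
#'
#' @return A count tibble suitable for [kano_metrics()]: `attribute_id`,
#'   `m`, `o`, `a`, `i`, `q`, `r`, `n`.
#' @examples
#' kano_metrics(telenursing_counts())
#' @export
telenursing_counts <- function() {
  x <- telenursing_count_rows
  out <- tibble::tibble(
    attribute_id = as.integer(x[, 1]),
    m = as.integer(x[, 2]), o = as.integer(x[, 3]), a = as.integer(x[, 4]),
    i = as.integer(x[, 5]), q = as.integer(x[, 6]), r = as.integer(x[, 7])
  )
  out$n <- as.integer(rowSums(out[count_cols]))
  if (!all(out$n == 348L)) {
    rlang::abort("Fixture corrupted: every attribute row must sum to 348 respondents.")
  }
  out
}

#' Published derived statistics for the telenursing attributes
#'
#' The study's reported final category, category strength, total strength
#' and Better/Worse coefficients, as printed (2 decimals). Useful as a
#' reference to compare against [kano_metrics()] output.
#'
#' @return A tibble with one row per attribute.
#' @export
telenursing_reference_metrics <- function() {
  out <- tibble::as_tibble(telenursing_published)
  out$final_category <- factor(out$final_category, levels = kano_categories())
  out
}

#' Per-group category counts from the telenursing study
#'
#' Category tallies per attribute for two paired respondent groups: the two
#' study cities (Yangzhou, n = 173 / Nantong, n = 175) or rural vs urban
#' communities (n = 173 / 175). The published rank-sum |Z| and p for each
#' attribute are carried in `z_published` / `p_published` (the ordinal
#' coding behind them was not reported). Marginal totals are re-checked on
#' every call.
#'
#' @param by `"city"` or `"residence"`.
#' @return A tibble with two rows per attribute: `attribute_id`, `group`,
#'   tallies `m`, `o`, `a`, `i`, `q`, `r`, `n`, `z_published`,
#'   `p_published`.
#' @examples
#' kano_compare_counts(telenursing_group_counts("city"))
#' @export
telenursing_group_counts <- function(by = c("city", "residence")) {
  by <- rlang::arg_match(by)
  x <- if (by == "city") telenursing_city_rows else telenursing_residence_rows
  groups <- if (by == "city") c("Yangzhou", "Nantong") else c("Rural", "Urban")
  per_group <- function(g) {
    off <- if (g == 1) 1 else 7
    tibble::tibble(
      attribute_id = as.integer(x[, 1]),
      group = groups[g],
      m = as.integer(x[, off + 1]), o = as.integer(x[, off + 2]),
      a = as.integer(x[, off + 3]), i = as.integer(x[, off + 4]),
      q = as.integer(x[, off + 5]), r = as.integer(x[, off + 6]),
      z_published = x[, 14], p_published = x[, 15]
    )
  }
  out <- dplyr::bind_rows(per_group(1), per_group(2)) |>
    dplyr::arrange(.data$attribute_id, factor(.data$group, groups))
  out$n <- as.integer(rowSums(out[count_cols]))
  expected <- stats::setNames(c(173L, 175L), groups)
  if (!all(out$n == expected[out$group])) {
    rlang::abort("Fixture corrupted: group rows must sum to the published group sizes (173/175).")
  }
  dplyr::relocate(out, "n", .after = "r")
}

#' Sociodemographic frequency table from the telenursing study
#'
#' Published distribution of respondent characteristics (N = 348): gender,
#' age band, education level, residence and living condition, with counts
#' and percentages as printed.
#'
#' @return A tibble with `covariate`, `level`, `n`, `pct`.
#' @export
telenursing_demographics <- function() {
  out <- tibble::as_tibble(telenursing_demo_rows)
  sums <- tapply(out$n, out$covariate, sum)
  if (!all(sums == 348L)) {
    rlang::abort("Fixture corrupted: each covariate must total 348 respondents.")
  }
  out
}
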