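#' Read and validate a Kano survey CSV
#'
#' Reads a respondent-level survey in the wide schema (`respondent_id`,
#' covariate columns, answer columns `a<k>_f` / `a<k>_d`), parses answers
#' given as integer codes 1-5 or scale labels, and applies the validity
#' rules: a row with any missing or unparseable answer is excluded as
#' incomplete; a respondent whose fraction of questionable (Q) answer pairs
#' exceeds `q_fraction` is excluded as questionable (attribute-level Q
#' answers below that fraction are retained, as published Kano tables
#' report nonzero Q tallies). The resulting effective rate is
#' `100 * valid / received`.
#'
#' @param path Path to a UTF-8, comma-separated file with a header.
#' @param q_fraction Fraction of Q pairs above which a respondent is
#'   excluded as questionable (default 0.5).
#' @inheritParams classify_kano
#' @return The validated survey tibble (answers as integer codes). The
#'   validation summary is attached as attribute `"validation"` (retrieve
#'   with [kano_validation()]) and per-cell problems as attribute
#'   `"problems"` (a tibble with `respondent_id`, `column`, `value`).
#' @export
read_kano_survey <- function(path, q_fraction = 0.5, table = kano_evaluation_table()) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"respondent_id" %in% names(raw)) {
    rlang::abort("Missing required column: respondent_id")
  }
  ks <- answer_cols(raw)
  ans_cols <- paste0("a", rep(ks, each = 2), c("_f", "_d"))

  lv <- likert_levels()
  parse_one <- function(x) {
    key <- tolower(trimws(x))
    code <- lv$code[match(key, lv$level)]
    code[is.na(code)] <- lv$code[match(key[is.na(code)], tolower(lv$label))]
    num <- suppressWarnings(as.integer(key))
    code[is.na(code)] <- ifelse(!is.na(num) & num >= 1L & num <= 5L, num, NA_integer_)[is.na(code)]
    code
  }
  parsed <- raw
  problems <- list()
  for (col in ans_cols) {
    code <- parse_one(raw[[col]])
    bad <- which(!is.na(raw[[col]]) & is.na(code))
    if (length(bad) > 0) {
      problems[[col]] <- tibble::tibble(
        respondent_id = raw$respondent_id[bad], column = col, value = raw[[col]][bad]
      )
    }
    parsed[[col]] <- code
  }
  problems <- dplyr::bind_rows(problems)

  received <- nrow(parsed)
  incomplete <- rowSums(is.na(parsed[ans_cols])) > 0
  kept <- parsed[!incomplete, , drop = FALSE]

  questionable <- if (nrow(kept) > 0) {
    apply(kept[ans_cols], 1, function(v) {
      f <- as.integer(v[paste0("a", ks, "_f")])
      d <- as.integer(v[paste0("a", ks, "_d")])
      mean(classify_kano(f, d, table) == "Q") > q_fraction
    })
  } else {
    logical(0)
  }
  valid <- kept[!questionable, , drop = FALSE]

  n_valid <- nrow(valid)
  report <- tibble::tibble(
    received = received,
    excluded_incomplete = sum(incomplete),
    excluded_questionable = sum(questionable),
    valid = n_valid,
    effective_rate = round_half_up(100 * n_valid / received, 2)
  )
  attr(valid, "validation") <- report
  attr(valid, "problems") <- problems
  attr(valid, "source") <- path
  valid
}

#' Validation report of a survey read from file
#'
#' @param survey A survey tibble returned by [read_kano_survey()].
#' @return A one-row tibble: `received`, `excluded_incomplete`,
#'   `excluded_questionable`, `valid`, `effective_rate` (percent).
#' @export
kano_validation <- function(survey) {
  rep <- attr(survey, "validation")
  if (is.null(rep)) rlang::abort("No validation report attached; was this read with read_kano_survey()?")
  rep
}

#' Write a survey tibble to CSV
#'
#' Writes the wide survey schema losslessly (UTF-8, comma-separated,
#' header), so that [read_kano_survey()] round-trips answers and
#' covariates.
#'
#' @param survey A wide survey tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kano_survey <- function(survey, path) {
  readr::write_csv(survey, path, progress = FALSE)
  invisible(path)
}

#' Frequency summary of respondent covariates
#'
#' Counts and percentages per covariate level, the usual first table of a
#' survey report.
#'
#' @param survey A wide survey tibble.
#' @param vars Covariate column names; defaults to all non-id, non-answer
#'   columns.
#' @param digits Decimal places for percentages.
#' @return A tibble with `covariate`, `level`, `n`, `pct`; within each
#'   covariate the counts sum to the number of respondents.
#' @examples
#' summarize_demographics(simulate_kano_survey(n = 50, seed = 3))
#' @export
summarize_demographics <- function(survey, vars = NULL, digits = 2) {
  if (nrow(survey) == 0) rlang::abort("Empty survey.")
  if (is.null(vars)) {
    vars <- setdiff(names(survey), c("respondent_id", grep("^a\\d+_(f|d)$", names(survey), value = TRUE)))
  }
  n_total <- nrow(survey)
  purrr::map_dfr(vars, function(v) {
    survey |>
      dplyr::count(level = as.character(.data[[v]]), name = "n") |>
      dplyr::mutate(
        covariate = v,
        pct = round_half_up(100 * .data$n / n_total, digits)
      ) |>
      dplyr::select("covariate", "level", "n", "pct")
  })
}

#' Sample-size range for a cross-sectional survey
#'
#' The events-per-variable rule of thumb: a cross-sectional study should
#' enrol 10-20 respondents per independent variable, inflated for the
#' anticipated dropout/loss rate. With 15 variables, multipliers 10-20 and
#' 20% dropout the range is 180-360.
#'
#' @param n_predictors Number of independent variables.
#' @param lower,upper Respondents per variable at the lower/upper end
#'   (default 10 and 20).
#' @param dropout Anticipated loss rate in `[0, 1)` (default 0.2).
#' @return A one-row tibble with `n_min` and `n_max` (rounded up).
#' @examples
#' sample_size_range(15) # 180 to 360
#' @export
sample_size_range <- function(n_predictors, lower = 10, upper = 20, dropout = 0.2) {
  stopifnot(n_predictors >= 1, lower > 0, upper >= lower)
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1) {
    rlang::abort("dropout must be in [0, 1).")
  }
  tibble::tibble(
    n_min = as.integer(ceiling(n_predictors * lower * (1 + dropout))),
    n_max = as.integer(ceiling(n_predictors * upper * (1 + dropout)))
  )
}

#' Better-Worse plot coordinates and quadrants
#'
#' Places each attribute at (Worse, Better) and labels its quadrant at a
#' percentage threshold (default 50): high Better / low Worse is
#' Attractive, high/high One-dimensional, low/high Must-be, low/low
#' Indifferent. A coordinate equal to the threshold counts as high.
#'
#' @param metrics A metrics tibble from [kano_metrics()] (or a
#'   `kano_analysis` object).
#' @param threshold Quadrant threshold in (0, 100).
#' @return A tibble with `attribute_id`, `worse` (x), `better` (y) and
#'   `quadrant` (factor: Attractive, One-dimensional, Must-be,
#'   Indifferent).
#' @examples
#' better_worse_points(kano_metrics(telenursing_counts()))
#' @export
better_worse_points <- function(metrics, threshold = 50) {
  if (inherits(metrics, "kano_analysis")) metrics <- metrics$metrics
  stopifnot(nrow(metrics) > 0, threshold > 0, threshold < 100)
  hi_b <- metrics$better >= threshold
  hi_w <- metrics$worse >= threshold
  quad <- dplyr::case_when(
    hi_b & !hi_w ~ "Attractive",
    hi_b & hi_w ~ "One-dimensional",
    !hi_b & hi_w ~ "Must-be",
    .default = "Indifferent"
  )
  tibble::tibble(
    attribute_id = metrics$attribute_id,
    worse = metrics$worse,
    better = metrics$better,
    quadrant = factor(quad, levels = c("Attractive", "One-dimensional", "Must-be", "Indifferent"))
  )
}

#' Write a full analysis report to disk
#'
#' Writes the per-attribute results CSV (counts plus derived statistics),
#' optionally a group-comparison CSV per comparison, a Better-Worse
#' scatter with quadrant lines (PNG), and a JSON run log recording inputs,
#' seed, configuration and package versions. Two runs with the same inputs
#' produce identical CSV content.
#'
#' @param analysis A `kano_analysis` object.
#' @param comparisons A named list of `kano_comparison` objects (or `NULL`).
#' @param out_dir Output directory, created if needed.
#' @param threshold Quadrant threshold passed to [better_worse_points()].
#' @param seed Seed to record in the run log.
#' @param config Arbitrary configuration list to record in the run log.
#' @return Invisibly, a character vector of the files written.
#' @export
render_kano_report <- function(analysis, comparisons = NULL, out_dir,
                               threshold = 50, seed = NULL, config = list()) {
  stopifnot(inherits(analysis, "kano_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  log <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    threshold = threshold,
    config = config,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("kanosurvey")),
    notes = character(0)
  )

  metrics_path <- file.path(out_dir, "attribute_metrics.csv")
  readr::write_csv(tidy(analysis), metrics_path, progress = FALSE)
  files <- c(files, metrics_path)

  pts <- better_worse_points(analysis, threshold)
  pts_path <- file.path(out_dir, "better_worse_points.csv")
  readr::write_csv(pts, pts_path, progress = FALSE)
  files <- c(files, pts_path)

  plot_path <- file.path(out_dir, "better_worse.png")
  p <- plot_better_worse(analysis, threshold = threshold)
  ggplot2::ggsave(plot_path, p, width = 6, height = 5, dpi = 150)
  files <- c(files, plot_path)

  if (is.null(comparisons) || length(comparisons) == 0) {
    log$notes <- c(log$notes, "no group comparisons supplied; comparison files omitted")
  } else {
    if (is.null(names(comparisons))) names(comparisons) <- paste0("comparison", seq_along(comparisons))
    for (nm in names(comparisons)) {
      cmp_path <- file.path(out_dir, paste0("comparison_", nm, ".csv"))
      readr::write_csv(tibble::as_tibble(comparisons[[nm]]), cmp_path, progress = FALSE)
      files <- c(files, cmp_path)
    }
  }

  log$files <- basename(files)
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  files <- c(files, log_path)
  invisible(files)
}
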