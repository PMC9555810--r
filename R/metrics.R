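# Round half away from zero on the percent scale, the convention used by
# the published tables (e.g. 83.045... prints as 83.05); base round() is
# round-half-even and would disagree on such values.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

maybe_round <- function(x, digits) {
  if (is.null(digits)) x else round_half_up(x, digits)
}

count_cols <- c("m", "o", "a", "i", "q", "r")

# Validate a per-attribute category-count table: lower-case columns
# m, o, a, i, q, r (missing ones default to 0), integer-valued and
# non-negative; adds n = row sum if absent and checks it otherwise.
check_counts <- function(counts) {
  stopifnot(is.data.frame(counts))
  counts <- tibble::as_tibble(counts)
  names(counts) <- ifelse(names(counts) %in% toupper(count_cols) | names(counts) == "N",
    tolower(names(counts)), names(counts)
  )
  for (col in count_cols) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  tallies <- as.matrix(counts[count_cols])
  if (any(is.na(tallies)) || any(tallies < 0) || any(tallies != round(tallies))) {
    rlang::abort("Category tallies must be non-negative integers.")
  }
  total <- as.integer(rowSums(tallies))
  if (!"n" %in% names(counts)) {
    counts$n <- total
  } else if (any(counts$n != total)) {
    rlang::abort("Tallies m+o+a+i+q+r must sum to n for every attribute.")
  }
  if (any(counts$n == 0)) rlang::abort("Each attribute needs at least one respondent (n > 0).")
  if (!"attribute_id" %in% names(counts)) counts$attribute_id <- seq_len(nrow(counts))
  counts[, c("attribute_id", count_cols, "n")]
}

# Wide survey layout: respondent_id, covariates, then a<k>_f / a<k>_d
# answer columns for k = 1..K.
answer_cols <- function(data) {
  k <- sort(unique(as.integer(sub("^a(\\d+)_f$", "\\1", grep("^a\\d+_f$", names(data), value = TRUE)))))
  if (length(k) == 0) {
    rlang::abort("No answer columns found: expected pairs a<k>_f / a<k>_d for k = 1..K.")
  }
  missing_d <- setdiff(paste0("a", k, "_d"), names(data))
  if (length(missing_d) > 0) {
    rlang::abort(paste0("Missing dysfunctional column(s): ", paste(missing_d, collapse = ", ")))
  }
  k
}

#' Pivot a wide Kano survey to one row per respondent and attribute
#'
#' @param data A survey tibble in the wide layout: `respondent_id`, optional
#'   covariate columns, and answer columns `a<k>_f` / `a<k>_d` for each
#'   attribute `k`.
#' @return A tibble with columns `respondent_id`, any covariates,
#'   `attribute_id`, `functional` and `dysfunctional` (integer codes).
#' @export
kano_longer <- function(data) {
  ks <- answer_cols(data)
  ans <- paste0("a", rep(ks, each = 2), c("_f", "_d"))
  long <- tidyr::pivot_longer(
    data,
    cols = dplyr::all_of(ans),
    names_pattern = "^a(\\d+)_(f|d)$",
    names_to = c("attribute_id", ".value")
  )
  long$attribute_id <- as.integer(long$attribute_id)
  long <- dplyr::rename(long, functional = "f", dysfunctional = "d")
  long$functional <- as_likert(long$functional, "functional")
  long$dysfunctional <- as_likert(long$dysfunctional, "dysfunctional")
  long
}

#' Tabulate Kano categories per attribute
#'
#' Classifies every (functional, dysfunctional) pair and tallies categories
#' per attribute. Questionable (Q) and reverse (R) answers are retained in
#' the tallies, as in published Kano summary tables.
#'
#' @param data Either a wide survey tibble (see [kano_longer()]) or a long
#'   tibble with columns `attribute_id`, `functional`, `dysfunctional`.
#' @inheritParams classify_kano
#' @return A tibble with one row per attribute: `attribute_id`, tallies
#'   `m`, `o`, `a`, `i`, `q`, `r`, and total `n`.
#' @examples
#' kano_counts(tibble::tibble(attribute_id = 1, functional = 1, dysfunctional = 5))
#' @export
kano_counts <- function(data, table = kano_evaluation_table()) {
  if (nrow(data) == 0) rlang::abort("No respondents: the survey is empty.")
  long <- if (all(c("attribute_id", "functional", "dysfunctional") %in% names(data))) {
    data
  } else {
    kano_longer(data)
  }
  long$.category <- classify_kano(long$functional, long$dysfunctional, table)
  out <- long |>
    dplyr::count(.data$attribute_id, .data$.category) |>
    tidyr::pivot_wider(names_from = ".category", values_from = "n", values_fill = 0L)
  for (cc in toupper(count_cols)) if (!cc %in% names(out)) out[[cc]] <- 0L
  names(out) <- tolower(names(out))
  out$attribute_id <- as.integer(out$attribute_id)
  check_counts(out[order(out$attribute_id), c("attribute_id", count_cols)])
}

#' Final Kano category per attribute
#'
#' The category among M, O, A, I, R with the largest tally. Questionable
#' answers are tallied but can never win. Ties are broken by the fixed
#' priority M > O > A > I > R (most to least demanding of provision), so
#' output is deterministic on arbitrary data.
#'
#' @param counts A per-attribute count table as from [kano_counts()]:
#'   columns `m`, `o`, `a`, `i`, `q`, `r` (and optionally `n`).
#' @return Factor of final categories, one per row of `counts`.
#' @examples
#' kano_final_category(data.frame(m = 6, o = 201, a = 82, i = 48, q = 4, r = 7))
#' @export
kano_final_category <- function(counts) {
  counts <- check_counts(counts)
  contenders <- as.matrix(counts[c("m", "o", "a", "i", "r")])
  if (any(rowSums(contenders) == 0)) {
    rlang::abort("All of M, O, A, I, R are zero: no final category (only Q answers).")
  }
  winner <- apply(contenders, 1, which.max) # first max = tie-break priority
  factor(c("M", "O", "A", "I", "R")[winner], levels = kano_categories())
}

#' Category strength
#'
#' The percent-point gap between the largest and second-largest category
#' tallies (over M, O, A, I, R), relative to all `n` respondents including
#' Q and R answers. A small value flags an attribute whose final category
#' is weakly determined.
#'
#' @inheritParams kano_final_category
#' @param digits Decimal places for reporting (half-away-from-zero);
#'   `NULL` returns unrounded values.
#' @return Numeric vector of percentages in \[0, 100\].
#' @examples
#' kano_category_strength(data.frame(m = 105, o = 88, a = 73, i = 73, q = 7, r = 2))
#' @export
kano_category_strength <- function(counts, digits = 2) {
  counts <- check_counts(counts)
  contenders <- as.matrix(counts[c("m", "o", "a", "i", "r")])
  gap <- apply(contenders, 1, function(x) {
    s <- sort(x, decreasing = TRUE)
    s[1] - s[2]
  })
  maybe_round(100 * gap / counts$n, digits)
}

#' Total strength
#'
#' The percentage of respondents classifying an attribute as must-be,
#' one-dimensional or attractive — read as the proportion who want the
#' service provided. The denominator is all `n` respondents.
#'
#' @inheritParams kano_category_strength
#' @return Numeric vector of percentages in \[0, 100\].
#' @examples
#' kano_total_strength(data.frame(m = 7, o = 196, a = 88, i = 49, q = 4, r = 4))
#' @export
kano_total_strength <- function(counts, digits = 2) {
  counts <- check_counts(counts)
  maybe_round(100 * (counts$m + counts$o + counts$a) / counts$n, digits)
}

better_worse_raw <- function(counts) {
  denom <- counts$a + counts$o + counts$m + counts$i
  if (any(denom == 0)) {
    rlang::abort("Better/Worse undefined: A+O+M+I is zero (only Q/R answers).")
  }
  list(
    better = 100 * (counts$a + counts$o) / denom,
    worse = 100 * (counts$o + counts$m) / denom
  )
}

#' Better coefficient (satisfaction)
#'
#' `Better = (A + O) / (A + O + M + I)`, on the percent scale: the expected
#' gain in satisfaction from providing the attribute. Q and R answers are
#' excluded from numerator and denominator.
#'
#' @inheritParams kano_category_strength
#' @return Numeric vector of percentages in \[0, 100\].
#' @examples
#' kano_better(data.frame(m = 7, o = 193, a = 84, i = 59))
#' @export
kano_better <- function(counts, digits = 2) {
  counts <- check_counts(counts)
  maybe_round(better_worse_raw(counts)$better, digits)
}

#' Worse coefficient (dissatisfaction)
#'
#' `Worse = (O + M) / (A + O + M + I)`, on the percent scale: the expected
#' dissatisfaction from withholding the attribute. Q and R answers are
#' excluded.
#'
#' @inheritParams kano_category_strength
#' @return Numeric vector of percentages in \[0, 100\].
#' @examples
#' kano_worse(data.frame(m = 153, o = 64, a = 63, i = 63))
#' @export
kano_worse <- function(counts, digits = 2) {
  counts <- check_counts(counts)
  maybe_round(better_worse_raw(counts)$worse, digits)
}

#' All derived Kano statistics per attribute
#'
#' Bundles the final category, category strength, total strength and the
#' Better/Worse coefficients for each attribute of a count table.
#'
#' @inheritParams kano_category_strength
#' @return A tibble with columns `attribute_id`, `final_category`,
#'   `category_strength`, `total_strength`, `better`, `worse`.
#' @examples
#' kano_metrics(data.frame(m = 8, o = 34, a = 170, i = 122, q = 7, r = 7))
#' @export
kano_metrics <- function(counts, digits = 2) {
  counts <- check_counts(counts)
  bw <- better_worse_raw(counts)
  tibble::tibble(
    attribute_id = counts$attribute_id,
    final_category = kano_final_category(counts),
    category_strength = kano_category_strength(counts, digits),
    total_strength = kano_total_strength(counts, digits),
    better = maybe_round(bw$better, digits),
    worse = maybe_round(bw$worse, digits)
  )
}

#' Analyse a Kano survey end to end
#'
#' Classifies every answer pair of a respondent-level survey, tabulates
#' per-attribute category counts and derives all per-attribute statistics,
#' using one shared evaluation table.
#'
#' @param data A wide survey tibble (see [kano_longer()]) or a long tibble
#'   with `attribute_id`, `functional`, `dysfunctional` columns.
#' @inheritParams classify_kano
#' @inheritParams kano_category_strength
#' @param catalogue Optional attribute catalogue (tibble with
#'   `attribute_id`, `label`) merged into the results.
#' @return An object of class `kano_analysis`: a list with elements
#'   `counts`, `metrics` (tibbles, one row per attribute), `n_respondents`
#'   and `catalogue`. Use [tidy()][generics::tidy] for the per-attribute
#'   table, [glance()][generics::glance] for a one-row summary, and
#'   [autoplot()][ggplot2::autoplot] for the Better-Worse plot.
#' @examples
#' svy <- simulate_kano_survey(n = 50, seed = 1)
#' fit <- kano_analyze(svy)
#' tidy(fit)
#' @export
kano_analyze <- function(data, table = kano_evaluation_table(), digits = 2,
                         catalogue = NULL) {
  counts <- kano_counts(data, table)
  metrics <- kano_metrics(counts, digits)
  if (!is.null(catalogue)) {
    metrics <- dplyr::left_join(
      metrics, catalogue[c("attribute_id", "label")],
      by = "attribute_id"
    ) |>
      dplyr::relocate("label", .after = "attribute_id")
  }
  structure(
    list(
      counts = counts,
      metrics = metrics,
      n_respondents = max(counts$n),
      catalogue = catalogue
    ),
    class = "kano_analysis"
  )
}

#' @export
print.kano_analysis <- function(x, ...) {
  cat(sprintf(
    "Kano demand analysis: %d attributes, %d respondents\n",
    nrow(x$counts), x$n_respondents
  ))
  print(dplyr::left_join(x$counts, x$metrics, by = "attribute_id"), n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-attribute results of a Kano analysis
#'
#' @param x A `kano_analysis` object.
#' @param ... Unused.
#' @return A tibble joining category counts and derived statistics, one
#'   row per attribute.
#' @export
tidy.kano_analysis <- function(x, ...) {
  dplyr::left_join(x$counts, x$metrics, by = "attribute_id") |>
    dplyr::relocate(dplyr::any_of("label"), .after = "attribute_id")
}

#' One-row summary of a Kano analysis
#'
#' @inheritParams tidy.kano_analysis
#' @return A one-row tibble: attribute and respondent totals, the number of
#'   attributes per final category, and ranges of the derived coefficients.
#' @export
glance.kano_analysis <- function(x, ...) {
  fc <- table(x$metrics$final_category)
  tibble::tibble(
    n_attributes = nrow(x$metrics),
    n_respondents = x$n_respondents,
    n_must_be = as.integer(fc[["M"]]),
    n_one_dimensional = as.integer(fc[["O"]]),
    n_attractive = as.integer(fc[["A"]]),
    n_indifferent = as.integer(fc[["I"]]),
    n_reverse = as.integer(fc[["R"]]),
    better_min = min(x$metrics$better),
    better_max = max(x$metrics$better),
    worse_min = min(x$metrics$worse),
    worse_max = max(x$metrics$worse),
    total_strength_min = min(x$metrics$total_strength),
    total_strength_max = max(x$metrics$total_strength)
  )
}
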