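#' Five-level Likert answer scale used in Kano questionnaires
#'
#' Kano-style questionnaires ask each respondent a *functional* question
#' ("if this service were provided, how would you feel?") and a
#' *dysfunctional* question ("if it were not provided, how would you feel?"),
#' both answered on the same five-level scale. The canonical integer codes
#' run from 1 ("I like it that way") to 5 ("I dislike it that way").
#'
#' @return A tibble with one row per level: `code` (integer 1-5), `level`
#'   (short machine label) and `label` (the questionnaire wording).
#' @examples
#' likert_levels()
#' @export
likert_levels <- function() {
  tibble::tibble(
    code = 1:5,
    level = c("like", "must_be", "neutral", "live_with", "dislike"),
    label = c(
      "I like it that way",
      "It must be that way",
      "I am neutral",
      "I can live with it",
      "I dislike it that way"
    )
  )
}

#' The six Kano quality categories
#'
#' `M` must-be, `O` one-dimensional, `A` attractive, `I` indifferent,
#' `R` reverse, `Q` questionable (a contradictory answer pair). `Q` marks an
#' invalid response and is never a final attribute category.
#'
#' @return Character vector of the six category codes, in the package's
#'   canonical order.
#' @export
kano_categories <- function() c("M", "O", "A", "I", "R", "Q")

# Coerce answers to integer Likert codes 1-5.
# Accepts integer codes, short levels and questionnaire labels
# (case-insensitively); anything else errors naming the offending value.
as_likert <- function(x, arg = "answer") {
  if (is.numeric(x)) {
    code <- as.integer(x)
    bad <- !is.na(x) & (is.na(code) | code < 1L | code > 5L | code != x)
  } else {
    lv <- likert_levels()
    key <- tolower(trimws(as.character(x)))
    code <- lv$code[match(key, lv$level)]
    code[is.na(code)] <- lv$code[match(key[is.na(code)], tolower(lv$label))]
    num <- suppressWarnings(as.integer(key))
    code[is.na(code)] <- ifelse(!is.na(num) & num >= 1L & num <= 5L, num, NA_integer_)[is.na(code)]
    bad <- !is.na(x) & is.na(code)
  }
  if (any(bad)) {
    rlang::abort(sprintf(
      "Invalid %s value(s): %s. Expected codes 1-5 or labels %s.",
      arg,
      paste(unique(utils::head(x[bad], 5)), collapse = ", "),
      paste(shQuote(likert_levels()$level), collapse = ", ")
    ))
  }
  code
}

# 5x5 category matrix, functional rows x dysfunctional columns, both
# ordered like -> dislike. This is the standard Kano evaluation table.
kano_cell_matrix <- function() {
  matrix(
    c(
      "Q", "A", "A", "A", "O",
      "R", "I", "I", "I", "M",
      "R", "I", "I", "I", "M",
      "R", "I", "I", "I", "M",
      "R", "R", "R", "R", "Q"
    ),
    nrow = 5, byrow = TRUE,
    dimnames = list(likert_levels()$level, likert_levels()$level)
  )
}

#' The Kano evaluation table
#'
#' The 25-cell mapping from a (functional, dysfunctional) answer pair to a
#' Kano category. Concordant extremes ("like" to both, or "dislike" to both)
#' are questionable (`Q`); liking provision while disliking absence is
#' one-dimensional (`O`); and so on.
#'
#' @return A tibble with 25 rows and columns `functional`, `dysfunctional`
#'   (integer codes 1-5), `functional_level`, `dysfunctional_level` (short
#'   labels) and `category` (factor over [kano_categories()]). Rows are in
#'   row-major order: functional level varying slowest.
#' @examples
#' ev <- kano_evaluation_table()
#' table(ev$category) # A:3 O:1 M:3 I:9 R:7 Q:2
#' @export
kano_evaluation_table <- function() {
  m <- kano_cell_matrix()
  lv <- likert_levels()
  tibble::tibble(
    functional = rep(1:5, each = 5),
    dysfunctional = rep(1:5, times = 5),
    functional_level = rep(lv$level, each = 5),
    dysfunctional_level = rep(lv$level, times = 5),
    category = factor(as.vector(t(m)), levels = kano_categories())
  )
}

#' Classify functional/dysfunctional answer pairs
#'
#' Vectorised lookup of answer pairs in the Kano evaluation table.
#'
#' @param functional,dysfunctional Answers to the functional and
#'   dysfunctional question: integer codes 1-5 or labels (e.g. `"like"`,
#'   `"I like it that way"`), recycled to common length.
#' @param table Evaluation table as returned by [kano_evaluation_table()];
#'   supply a modified copy to use a non-standard mapping.
#' @return Factor of Kano categories with levels [kano_categories()].
#' @examples
#' classify_kano("like", "dislike") # O
#' classify_kano(c(1, 1, 5, 4), c(1, 5, 3, 5)) # Q O R M
#' @export
classify_kano <- function(functional, dysfunctional, table = kano_evaluation_table()) {
  f <- as_likert(functional, "functional")
  d <- as_likert(dysfunctional, "dysfunctional")
  n <- max(length(f), length(d))
  f <- rep_len(f, n)
  d <- rep_len(d, n)
  key <- (f - 1L) * 5L + d
  cat_by_cell <- table$category[order((table$functional - 1L) * 5L + table$dysfunctional)]
  cat_by_cell[key]
}

#' Cells of the evaluation table mapping to a category
#'
#' Inverse lookup: all (functional, dysfunctional) answer pairs that
#' classify as the given category, in the table's row-major order. The cell
#' counts per category are A: 3, O: 1, M: 3, I: 9, R: 7, Q: 2.
#'
#' @param category A single category code from [kano_categories()].
#' @inheritParams classify_kano
#' @return A tibble of matching evaluation-table rows.
#' @examples
#' cells_for_category("O") # the single cell (like, dislike)
#' @export
cells_for_category <- function(category, table = kano_evaluation_table()) {
  category <- rlang::arg_match(category, kano_categories())
  table[table$category == category, , drop = FALSE]
}
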