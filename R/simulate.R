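# Synthetic respondent generation. Two routes back to respondent-level
# data: random draws from per-attribute category mixtures (the study
# conditions are the default), and exact deterministic reconstruction from
# published category counts. All downstream statistics depend only on the
# category tallies, so any cell assignment consistent with the counts gives
# identical results; reconstruction fixes one (the first table cell of each
# category, row-major) so output is byte-stable.

first_cell <- function(category, table = kano_evaluation_table()) {
  cells_for_category(category, table)[1, c("functional", "dysfunctional")]
}

#' Sample answer pairs that classify to given categories
#'
#' For each requested category, draws one (functional, dysfunctional) cell
#' uniformly among the evaluation-table cells mapping to it, so that
#' classification always round-trips to the generating category.
#'
#' @param categories Character or factor vector of category codes.
#' @inheritParams classify_kano
#' @return A tibble with columns `functional` and `dysfunctional` (integer
#'   codes), one row per input category.
#' @examples
#' sample_kano_pairs(c("O", "O")) # always (1, 5): O has a single cell
#' @export
sample_kano_pairs <- function(categories, table = kano_evaluation_table()) {
  categories <- as.character(categories)
  bad <- setdiff(unique(categories), kano_categories())
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown category: ", paste(bad, collapse = ", ")))
  }
  cells <- lapply(
    stats::setNames(kano_categories(), kano_categories()),
    function(cc) cells_for_category(cc, table)
  )
  pick <- vapply(categories, function(cc) {
    k <- nrow(cells[[cc]])
    if (k == 1) 1L else sample.int(k, 1)
  }, integer(1))
  tibble::tibble(
    functional = purrr::map2_int(categories, pick, ~ cells[[.x]]$functional[.y]),
    dysfunctional = purrr::map2_int(categories, pick, ~ cells[[.x]]$dysfunctional[.y])
  )
}

#' Per-attribute category mixtures of the telenursing study
#'
#' The empirical category proportions of the bundled telenursing count
#' table (each attribute's tallies divided by 348). These are the default
#' mixtures of [simulate_kano_survey()], so simulated surveys emulate the
#' study conditions.
#'
#' @return A tibble with `attribute_id` and probability columns `m`, `o`,
#'   `a`, `i`, `q`, `r` summing to 1 per row.
#' @export
telenursing_mixtures <- function() {
  cnt <- telenursing_counts()
  for (cc in count_cols) cnt[[cc]] <- cnt[[cc]] / cnt$n
  cnt[, c("attribute_id", count_cols)]
}

check_mixtures <- function(mixtures) {
  stopifnot(is.data.frame(mixtures))
  mixtures <- tibble::as_tibble(mixtures)
  names(mixtures) <- tolower(names(mixtures))
  miss <- setdiff(count_cols, names(mixtures))
  if (length(miss) > 0) {
    rlang::abort(paste0("Mixture missing probability column(s): ", paste(miss, collapse = ", ")))
  }
  p <- as.matrix(mixtures[count_cols])
  if (any(is.na(p)) || any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9)) {
    rlang::abort("Mixture probabilities must be non-negative and sum to 1 (within 1e-9).")
  }
  if (!"attribute_id" %in% names(mixtures)) mixtures$attribute_id <- seq_len(nrow(mixtures))
  mixtures
}

#' Covariate model of the telenursing study population
#'
#' Sampling weights for respondent covariates matching the study's
#' sociodemographic table: a joint city-by-residence cell (87/88/86/87 of
#' 348), and independent gender, age band, education and living condition.
#'
#' @return A named list of data frames, each with covariate column(s) and a
#'   `prob` column; rows are the cells of one (joint) covariate generator.
#' @export
telenursing_covariate_model <- function() {
  demo <- telenursing_demographics()
  lv <- function(cov) demo[demo$covariate == cov, ]
  res <- lv("residence_city")
  list(
    residence_city = data.frame(
      city = c("Yangzhou", "Nantong", "Yangzhou", "Nantong"),
      residence = c("Urban", "Urban", "Rural", "Rural"),
      prob = res$n[match(
        c(
          "Urban (Yangzhou)", "Urban (Nantong)",
          "Rural (Yangzhou)", "Rural (Nantong)"
        ),
        res$level
      )] / 348
    ),
    gender = data.frame(gender = lv("gender")$level, prob = lv("gender")$n / 348),
    age_band = data.frame(age_band = lv("age_band")$level, prob = lv("age_band")$n / 348),
    education = data.frame(education = lv("education")$level, prob = lv("education")$n / 348),
    living_condition = data.frame(
      living_condition = lv("living_condition")$level,
      prob = lv("living_condition")$n / 348
    )
  )
}

#' Simulate a respondent-level Kano survey
#'
#' Draws each respondent's category for each attribute from that
#' attribute's category mixture, then draws an answer pair uniformly among
#' the evaluation-table cells of the drawn category. Attributes are sampled
#' independently. Covariates are drawn from the supplied generator cells.
#' Defaults reproduce the telenursing study conditions: n = 348 respondents
#' and the empirical category mixtures of the bundled count table.
#'
#' @param n Number of respondents.
#' @param mixtures Per-attribute category mixtures, see
#'   [telenursing_mixtures()] for the format and default.
#' @param covariates Covariate generators as in
#'   [telenursing_covariate_model()] (the default); `NULL` for none.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @inheritParams classify_kano
#' @return A wide survey tibble (`respondent_id`, covariates, `a<k>_f`,
#'   `a<k>_d` per attribute) with the seed recorded in attribute `"seed"`.
#' @examples
#' svy <- simulate_kano_survey(n = 20, seed = 42)
#' kano_counts(svy)
#' @export
simulate_kano_survey <- function(n = 348, mixtures = telenursing_mixtures(),
                                 covariates = telenursing_covariate_model(),
                                 seed = NULL, table = kano_evaluation_table()) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  mixtures <- check_mixtures(mixtures)
  if (!is.null(seed)) set.seed(seed)

  out <- tibble::tibble(respondent_id = sprintf("r%04d", seq_len(n)))
  for (cov in covariates) {
    idx <- sample.int(nrow(cov), n, replace = TRUE, prob = cov$prob)
    for (col in setdiff(names(cov), "prob")) out[[col]] <- cov[[col]][idx]
  }
  for (j in seq_len(nrow(mixtures))) {
    probs <- as.numeric(mixtures[j, count_cols])
    cats <- sample(toupper(count_cols), n, replace = TRUE, prob = probs)
    pairs <- sample_kano_pairs(cats, table)
    out[[paste0("a", mixtures$attribute_id[j], "_f")]] <- pairs$functional
    out[[paste0("a", mixtures$attribute_id[j], "_d")]] <- pairs$dysfunctional
  }
  attr(out, "seed") <- seed
  out
}

#' Reconstruct a respondent-level survey from category counts
#'
#' Builds a dataset of exactly `n` respondents whose tabulation reproduces
#' the given per-attribute tallies. Assignment is deterministic: each
#' category's quota is filled with the first evaluation-table cell of that
#' category (row-major order), categories in order M, O, A, I, Q, R. Since
#' every derived statistic depends only on the tallies, the reconstruction
#' is statistically equivalent to the original (unavailable) raw data.
#'
#' @param counts Count table (columns `m`, `o`, `a`, `i`, `q`, `r`, one row
#'   per attribute); all rows must share the same total `n`.
#' @param covariates Optional named list of constant covariate values to
#'   attach to every respondent (e.g. `list(city = "Yangzhou")`).
#' @param id_prefix Prefix for generated respondent ids.
#' @inheritParams classify_kano
#' @return A wide survey tibble, as from [simulate_kano_survey()].
#' @examples
#' svy <- reconstruct_kano_survey(telenursing_counts())
#' all.equal(kano_counts(svy), telenursing_counts())
#' @export
reconstruct_kano_survey <- function(counts, covariates = NULL,
                                    id_prefix = "r",
                                    table = kano_evaluation_table()) {
  counts <- check_counts(counts)
  n <- unique(counts$n)
  if (length(n) != 1) {
    rlang::abort("All attributes must have the same total n to form one dataset.")
  }
  out <- tibble::tibble(respondent_id = sprintf("%s%04d", id_prefix, seq_len(n)))
  for (nm in names(covariates)) out[[nm]] <- covariates[[nm]]
  cells <- lapply(
    stats::setNames(toupper(count_cols), toupper(count_cols)),
    function(cc) first_cell(cc, table)
  )
  for (j in seq_len(nrow(counts))) {
    cats <- rep(toupper(count_cols), times = as.integer(counts[j, count_cols]))
    out[[paste0("a", counts$attribute_id[j], "_f")]] <-
      vapply(cats, function(cc) cells[[cc]]$functional, integer(1), USE.NAMES = FALSE)
    out[[paste0("a", counts$attribute_id[j], "_d")]] <-
      vapply(cats, function(cc) cells[[cc]]$dysfunctional, integer(1), USE.NAMES = FALSE)
  }
  out
}

#' Reconstruct a two-group survey from per-group category counts
#'
#' Applies [reconstruct_kano_survey()] to each group of a per-group count
#' table and stacks the results, attaching the group label as a covariate
#' column. The result is ready for [kano_compare()].
#'
#' @param group_counts Tibble with `attribute_id`, `group` and tallies
#'   `m`, `o`, `a`, `i`, `q`, `r` (two rows per attribute), e.g. from
#'   [telenursing_group_counts()].
#' @param covariate Name of the covariate column to create from `group`.
#' @inheritParams classify_kano
#' @return A wide survey tibble with a `covariate` column and unique ids.
#' @examples
#' svy <- reconstruct_kano_groups(telenursing_group_counts("city"), "city")
#' kano_compare(svy, "city")
#' @export
reconstruct_kano_groups <- function(group_counts, covariate = "group",
                                    table = kano_evaluation_table()) {
  group_counts <- check_group_counts(group_counts)
  groups <- unique(group_counts$group)
  parts <- lapply(seq_along(groups), function(g) {
    sub <- group_counts[group_counts$group == groups[g], c("attribute_id", count_cols)]
    cov <- stats::setNames(list(groups[g]), covariate)
    reconstruct_kano_survey(sub, covariates = cov, id_prefix = paste0("g", g, "_"), table = table)
  })
  dplyr::bind_rows(parts)
}
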