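#' Default ordinal encoding of Kano categories
#'
#' A rank-sum comparison of Kano outcomes needs the six categories placed on
#' an ordinal scale. The default orders them by descending demand intensity:
#' must-be 5, one-dimensional 4, attractive 3, indifferent 2, reverse 1,
#' questionable 0. Supply any complete named numeric vector to
#' [kano_compare()] to use a different coding.
#'
#' @return Named numeric vector over all six categories.
#' @export
kano_default_encoding <- function() {
  c(M = 5, O = 4, A = 3, I = 2, R = 1, Q = 0)
}

#' Encode Kano categories as ordinal scores
#'
#' @param categories Character or factor vector of category codes.
#' @param encoding Named numeric vector covering every category present;
#'   defaults to [kano_default_encoding()].
#' @return Numeric vector of scores, same length as `categories`.
#' @examples
#' encode_kano(c("M", "O", "A")) # 5 4 3
#' @export
encode_kano <- function(categories, encoding = kano_default_encoding()) {
  categories <- as.character(categories)
  missing <- setdiff(unique(categories), names(encoding))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "Encoding does not cover category: ", paste(missing, collapse = ", ")
    ))
  }
  unname(encoding[categories])
}

# Exact two-sided rank-sum p by complete enumeration of the C(N, n_a)
# assignments of pooled mid-ranks to group a; feasible for N <= ~12.
rank_sum_exact_p <- function(r_pooled, n_a, w_obs) {
  e <- n_a * (length(r_pooled) + 1) / 2
  sums <- utils::combn(r_pooled, n_a, sum)
  mean(abs(sums - e) >= abs(w_obs - e) - 1e-9)
}

#' Two-sample rank-sum test on ordinal scores
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test using pooled mid-ranks.
#' By default the normal approximation with tie-corrected variance and no
#' continuity correction is used; when the pooled sample is small
#' (`n_a + n_b <= exact_max`) the p-value comes from complete enumeration of
#' all rank assignments instead. `z` is reported as a magnitude, matching
#' how such tables are usually printed; `z_signed` keeps the direction
#' (positive when group a tends to score higher).
#'
#' @param x,y Numeric score vectors for the two groups (both non-empty).
#' @param exact_max Use exact enumeration when `length(x) + length(y)` is at
#'   most this; set to 0 to always use the normal approximation.
#' @param continuity Apply a 0.5 continuity correction to the normal
#'   approximation (off by default).
#' @return A one-row tibble: `n_a`, `n_b`, `z`, `z_signed`, `p`, `method`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4)) # exact p = 1/3
#' @export
rank_sum_test <- function(x, y, exact_max = 12, continuity = FALSE) {
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("Both groups must be non-empty.")
  }
  n_a <- length(x)
  n_b <- length(y)
  pooled <- c(x, y)
  n <- n_a + n_b
  r <- rank(pooled)
  w <- sum(r[seq_len(n_a)])
  e <- n_a * (n + 1) / 2
  ties <- table(pooled)
  v <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))

  if (v <= 0) {
    rlang::warn("All observations identical across both groups; Z = 0, p = 1.")
    return(tibble::tibble(
      n_a = n_a, n_b = n_b, z = 0, z_signed = 0, p = 1, method = "degenerate"
    ))
  }
  num <- w - e
  if (continuity) num <- sign(num) * max(abs(num) - 0.5, 0)
  z_signed <- num / sqrt(v)
  if (n <= exact_max) {
    p <- rank_sum_exact_p(r, n_a, w)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z_signed))
    method <- "normal"
  }
  tibble::tibble(
    n_a = n_a, n_b = n_b, z = abs(z_signed), z_signed = z_signed,
    p = p, method = method
  )
}

#' Compare Kano demand between two respondent groups
#'
#' For each attribute, classifies every respondent's answer pair, encodes
#' the categories on an ordinal scale and runs a two-sided rank-sum test
#' between the two levels of a grouping covariate. Questionable (Q)
#' respondents are included by default (their per-group tallies are part of
#' the published comparison tables); set `include_q = FALSE` to drop them.
#' No multiple-testing adjustment is applied by default; `adjust` accepts
#' any [stats::p.adjust()] method.
#'
#' @param data A wide survey tibble (see [kano_longer()]).
#' @param group Name of the two-level grouping column (string).
#' @param encoding Ordinal encoding of categories, see
#'   [kano_default_encoding()].
#' @param include_q Keep Q-classified responses in the test (default TRUE).
#' @param adjust Multiple-testing correction across attributes
#'   (default `"none"`).
#' @inheritParams rank_sum_test
#' @inheritParams classify_kano
#' @return An object of class `kano_comparison`: a tibble with two rows per
#'   attribute (one per group) carrying the per-group category tallies
#'   `m`, `o`, `a`, `i`, `q`, `r`, group size `n`, and the attribute-level
#'   `z` and `p` (repeated on both rows). [tidy()][generics::tidy] returns
#'   one row per attribute.
#' @examples
#' svy <- simulate_kano_survey(n = 80, seed = 7)
#' kano_compare(svy, "city")
#' @export
kano_compare <- function(data, group, encoding = kano_default_encoding(),
                         include_q = TRUE, adjust = "none",
                         exact_max = 12, continuity = FALSE,
                         table = kano_evaluation_table()) {
  if (!group %in% names(data)) {
    rlang::abort(paste0("Grouping column not found: ", group))
  }
  long <- kano_longer(data)
  long$.group <- as.character(long[[group]])
  long$.category <- as.character(classify_kano(long$functional, long$dysfunctional, table))
  compare_classified(long, encoding, include_q, adjust, exact_max, continuity,
    group_name = group
  )
}

#' Compare groups directly from per-group category counts
#'
#' Runs the same per-attribute rank-sum comparison as [kano_compare()], but
#' starting from already-tabulated per-group category counts (two rows per
#' attribute). All rank-sum results depend only on these tallies, so this
#' is equivalent to comparing a respondent-level dataset with the same
#' counts.
#'
#' @param group_counts Tibble with columns `attribute_id`, `group` and
#'   tallies `m`, `o`, `a`, `i`, `q`, `r`; exactly two groups.
#' @inheritParams kano_compare
#' @return A `kano_comparison` tibble, see [kano_compare()].
#' @examples
#' kano_compare_counts(telenursing_group_counts("city"))
#' @export
kano_compare_counts <- function(group_counts, encoding = kano_default_encoding(),
                                include_q = TRUE, adjust = "none",
                                exact_max = 12, continuity = FALSE) {
  long <- group_counts |>
    check_group_counts() |>
    tidyr::pivot_longer(dplyr::all_of(count_cols),
      names_to = ".category", values_to = ".k"
    ) |>
    dplyr::mutate(.category = toupper(.data$.category)) |>
    tidyr::uncount(.data$.k) |>
    dplyr::rename(.group = "group")
  compare_classified(long, encoding, include_q, adjust, exact_max, continuity,
    group_name = "group"
  )
}

check_group_counts <- function(group_counts) {
  stopifnot(is.data.frame(group_counts))
  group_counts <- tibble::as_tibble(group_counts)
  names(group_counts) <- tolower(names(group_counts))
  need <- c("attribute_id", "group", count_cols)
  miss <- setdiff(need, names(group_counts))
  if (length(miss) > 0) {
    rlang::abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  group_counts
}

compare_classified <- function(long, encoding, include_q, adjust,
                               exact_max, continuity, group_name) {
  levels_g <- sort(unique(long$.group))
  if (length(levels_g) != 2 ||
    any(vapply(levels_g, function(g) sum(long$.group == g) == 0, logical(1)))) {
    rlang::abort(paste0(
      "Grouping '", group_name, "' must have exactly two non-empty levels; found: ",
      paste(levels_g, collapse = ", ")
    ))
  }
  if (!include_q) long <- long[long$.category != "Q", , drop = FALSE]

  res <- long |>
    dplyr::group_by(.data$attribute_id) |>
    dplyr::group_modify(function(d, key) {
      scores <- split(encode_kano(d$.category, encoding), factor(d$.group, levels_g))
      tt <- rank_sum_test(scores[[1]], scores[[2]], exact_max, continuity)
      cnt <- d |>
        dplyr::count(.data$.group, .data$.category) |>
        tidyr::pivot_wider(
          names_from = ".category", values_from = "n", values_fill = 0L
        )
      for (cc in toupper(count_cols)) if (!cc %in% names(cnt)) cnt[[cc]] <- 0L
      names(cnt) <- tolower(names(cnt))
      cnt <- dplyr::rename(cnt, group = ".group")
      cnt$n <- as.integer(rowSums(cnt[count_cols]))
      dplyr::bind_cols(
        cnt[, c("group", count_cols, "n")],
        tt[rep(1, nrow(cnt)), c("z", "z_signed", "p", "method")]
      )
    }) |>
    dplyr::ungroup()

  if (adjust != "none") {
    first <- !duplicated(res$attribute_id)
    adj <- stats::p.adjust(res$p[first], method = adjust)
    res$p_adjusted <- adj[match(res$attribute_id, res$attribute_id[first])]
  }
  structure(res,
    class = c("kano_comparison", class(res)),
    group_name = group_name, encoding = encoding, adjust = adjust
  )
}

#' One row per attribute from a group comparison
#'
#' @param x A `kano_comparison` object.
#' @param ... Unused.
#' @return A tibble with `attribute_id`, the two group sizes, `z`,
#'   `z_signed`, `p` (and `p_adjusted` if an adjustment was requested).
#' @export
tidy.kano_comparison <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$attribute_id) |>
    dplyr::summarise(
      n_a = .data$n[1], n_b = .data$n[2],
      dplyr::across(dplyr::any_of(c("z", "z_signed", "p", "p_adjusted", "method")),
                    ~ .x[1]),
      .groups = "drop"
    )
}

#' Summary of a group comparison
#'
#' @inheritParams tidy.kano_comparison
#' @return One-row tibble: number of attributes tested, the grouping
#'   variable, minimum p, and how many attributes fall below 0.05.
#' @export
glance.kano_comparison <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_attributes = nrow(td),
    group = attr(x, "group_name"),
    p_min = min(td$p),
    n_significant_05 = sum(td$p < 0.05),
    adjust = attr(x, "adjust")
  )
}
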