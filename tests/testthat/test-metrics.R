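row_counts <- function(m, o, a, i, q = 0, r = 0) {
  data.frame(m = m, o = o, a = a, i = i, q = q, r = r)
}

test_that("derived statistics reproduce published per-attribute values", {
  # frozen printed values for individual count rows of the bundled study
  expect_equal(kano_category_strength(row_counts(105, 88, 73, 73, 7, 2)), 4.89)
  expect_equal(kano_category_strength(row_counts(6, 201, 82, 48, 4, 7)), 34.20)
  expect_equal(kano_total_strength(row_counts(7, 196, 88, 49, 4, 4)), 83.62)
  expect_equal(kano_total_strength(row_counts(5, 40, 120, 172, 5, 6)), 47.41)
  expect_equal(kano_better(row_counts(7, 193, 84, 59)), 80.76)
  expect_equal(kano_better(row_counts(167, 48, 72, 53)), 35.29)
  expect_equal(kano_worse(row_counts(153, 64, 63, 63)), 63.27)
  expect_equal(kano_worse(row_counts(4, 33, 174, 128)), 10.91)
  expect_equal(as.character(kano_final_category(row_counts(6, 201, 82, 48, 4, 7))), "O")
  expect_equal(as.character(kano_final_category(row_counts(5, 40, 120, 172, 5, 6))), "I")

  m1 <- kano_metrics(row_counts(8, 34, 170, 122, 7, 7))
  expect_equal(as.character(m1$final_category), "A")
  expect_equal(m1$category_strength, 13.79)
  expect_equal(m1$total_strength, 60.92)
  expect_equal(m1$better, 61.08)
  expect_equal(m1$worse, 12.57)
})

test_that("degenerate and tied count tables behave as documented", {
  # all answers in one category
  all_o <- kano_metrics(row_counts(0, 10, 0, 0))
  expect_equal(as.character(all_o$final_category), "O")
  expect_equal(all_o$category_strength, 100)
  expect_equal(all_o$total_strength, 100)
  expect_equal(all_o$better, 100)
  expect_equal(all_o$worse, 100)
  expect_equal(kano_total_strength(row_counts(0, 0, 0, 25)), 0)
  expect_equal(kano_worse(row_counts(0, 0, 10, 10)), 0)
  expect_equal(kano_better(row_counts(0, 4, 7, 0)), 100) # M = I = 0
})

test_that("five-way tie resolves by the documented priority M > O > A > I > R", {
  tied <- row_counts(10, 10, 10, 10, r = 10)
  expect_equal(as.character(kano_final_category(tied)), "M")
  expect_equal(as.character(kano_final_category(row_counts(0, 7, 7, 3))), "O")
  expect_equal(kano_category_strength(tied), 0)
})

test_that("Q never wins the final category and pure-Q input errors", {
  q_heavy <- row_counts(1, 0, 0, 0, q = 99)
  expect_equal(as.character(kano_final_category(q_heavy)), "M")
  expect_error(kano_final_category(row_counts(0, 0, 0, 0, q = 5)), "only Q")
  expect_error(kano_better(row_counts(0, 0, 0, 0, q = 3, r = 2)), "A\\+O\\+M\\+I")
})

test_that("count validation rejects malformed tallies and empty surveys", {
  expect_error(check_counts <- kano_metrics(row_counts(-1, 2, 3, 4)), "non-negative")
  expect_error(kano_counts(tibble::tibble()), "empty|No respondents")
  bad_n <- data.frame(m = 1, o = 1, a = 1, i = 1, q = 0, r = 0, n = 7)
  expect_error(kano_metrics(bad_n), "sum to n")
})

test_that("analysis of a survey equals a one-pair-at-a-time oracle recount", {
  withr::with_seed(101, {
    for (rep in 1:3) {
      n <- sample(20:120, 1)
      k <- sample(2:6, 1)
      long <- tibble::tibble(
        attribute_id = rep(seq_len(k), each = n),
        functional = sample(1:5, n * k, replace = TRUE),
        dysfunctional = sample(1:5, n * k, replace = TRUE)
      )
      got <- kano_counts(long)
      want <- oracle_counts(long)
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
      # tallies always sum to n
      expect_true(all(rowSums(got[c("m", "o", "a", "i", "q", "r")]) == got$n))
    }
  })
})

test_that("percentage closure and bounds hold on random count tables", {
  withr::with_seed(202, {
    for (rep in 1:20) {
      cnt <- random_counts(sample(5:400, 1))
      if (cnt$m + cnt$o + cnt$a + cnt$i == 0) next
      met <- kano_metrics(cnt, digits = NULL)
      expect_true(all(unlist(met[c("category_strength", "total_strength", "better", "worse")]) >= 0))
      expect_true(all(unlist(met[c("category_strength", "total_strength", "better", "worse")]) <= 100))
      closure <- met$total_strength + 100 * (cnt$i + cnt$r + cnt$q) / sum(cnt[1:6])
      expect_equal(closure, 100, tolerance = 1e-9)
    }
  })
})

test_that("wide-survey analysis matches metrics computed from its counts", {
  svy <- simulate_kano_survey(n = 60, seed = 9)
  fit <- kano_analyze(svy, catalogue = telenursing_attributes())
  expect_s3_class(fit, "kano_analysis")
  expect_equal(fit$metrics[names(fit$metrics) != "label"], kano_metrics(kano_counts(svy)))
  td <- tidy(fit)
  expect_equal(nrow(td), 15)
  expect_true(all(c("m", "better", "label") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_attributes, 15)
  expect_equal(
    gl$n_must_be + gl$n_one_dimensional + gl$n_attractive + gl$n_indifferent + gl$n_reverse,
    15L
  )
})

test_that("a respondent neutral on everything yields indifferent throughout", {
  svy <- tibble::tibble(respondent_id = "r1")
  for (k in 1:15) {
    svy[[paste0("a", k, "_f")]] <- 3L
    svy[[paste0("a", k, "_d")]] <- 3L
  }
  fit <- kano_analyze(svy)
  expect_true(all(fit$metrics$final_category == "I"))
})

test_that("reporting rounds half away from zero as in the published tables", {
  # 289/348 * 100 = 83.0459... -> 83.05 ; banker's rounding would differ at .xx5
  expect_equal(kano_total_strength(row_counts(6, 201, 82, 48, 4, 7)), 83.05)
  expect_equal(kanosurvey:::round_half_up(0.125 * 100, 2), 12.5)
  expect_equal(kanosurvey:::round_half_up(2.675, 2), 2.68)
  expect_equal(kanosurvey:::round_half_up(-2.675, 2), -2.68)
})
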