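test_that("sampled pairs always classify back to their generating category", {
  withr::with_seed(11, {
    cats <- sample(kano_categories(), 500, replace = TRUE)
    pairs <- sample_kano_pairs(cats)
    expect_equal(as.character(classify_kano(pairs$functional, pairs$dysfunctional)), cats)
  })
  # single-cell category is deterministic
  o_pairs <- sample_kano_pairs(rep("O", 10))
  expect_true(all(o_pairs$functional == 1 & o_pairs$dysfunctional == 5))
  expect_error(sample_kano_pairs("X"), "Unknown category")
})

test_that("cells of a category are sampled approximately uniformly", {
  withr::with_seed(12, {
    pairs <- sample_kano_pairs(rep("M", 30000))
    freq <- table(paste(pairs$functional, pairs$dysfunctional)) / 30000
    expect_equal(length(freq), 3)
    expect_true(all(abs(freq - 1 / 3) < 0.01))
  })
})

test_that("simulation is seed-reproducible and mixture-faithful", {
  s1 <- simulate_kano_survey(n = 120, seed = 77)
  s2 <- simulate_kano_survey(n = 120, seed = 77)
  expect_identical(s1, s2)
  s3 <- simulate_kano_survey(n = 120, seed = 78)
  expect_false(identical(s1, s3))

  # empirical category frequencies converge to the mixture
  mix <- tibble::tibble(m = 0.3, o = 0.25, a = 0.2, i = 0.15, q = 0.04, r = 0.06)
  svy <- simulate_kano_survey(n = 10000, mixtures = mix, covariates = NULL, seed = 13)
  cnt <- kano_counts(svy)
  emp <- as.numeric(cnt[1, c("m", "o", "a", "i", "q", "r")]) / cnt$n
  expect_true(all(abs(emp - as.numeric(mix)) < 0.02))
})

test_that("degenerate mixtures and invalid mixtures behave as specified", {
  all_o <- simulate_kano_survey(
    n = 40,
    mixtures = tibble::tibble(m = 0, o = 1, a = 0, i = 0, q = 0, r = 0),
    covariates = NULL, seed = 4
  )
  cnt <- kano_counts(all_o)
  expect_equal(cnt$o, 40L)
  expect_error(
    simulate_kano_survey(n = 10, mixtures = tibble::tibble(m = 0.5, o = 0.6, a = 0, i = 0, q = 0, r = 0)),
    "sum to 1"
  )
  expect_error(
    simulate_kano_survey(n = 10, mixtures = tibble::tibble(m = -0.1, o = 1.1, a = 0, i = 0, q = 0, r = 0)),
    "non-negative"
  )
})

test_that("default simulation emulates the study conditions", {
  svy <- simulate_kano_survey(seed = 99)
  expect_equal(nrow(svy), 348)
  expect_true(all(c("city", "residence", "gender", "age_band", "education", "living_condition") %in% names(svy)))
  expect_setequal(unique(svy$city), c("Yangzhou", "Nantong"))
  expect_equal(length(grep("^a\\d+_f$", names(svy))), 15)
})

test_that("reconstruction from counts is the exact inverse of tabulation", {
  cnt <- telenursing_counts()
  svy <- reconstruct_kano_survey(cnt)
  expect_equal(nrow(svy), 348)
  expect_equal(as.data.frame(kano_counts(svy)), as.data.frame(cnt))

  withr::with_seed(55, {
    for (rep in 1:25) {
      cnt_r <- random_counts(sample(1:500, 1), n_attr = sample(1:3, 1))
      back <- kano_counts(reconstruct_kano_survey(cnt_r))
      expect_equal(
        as.data.frame(back[c("m", "o", "a", "i", "q", "r")]),
        cnt_r[c("m", "o", "a", "i", "q", "r")],
        ignore_attr = TRUE
      )
    }
  })
})

test_that("reconstruction is deterministic and rejects empty counts", {
  cnt <- telenursing_counts()
  expect_identical(reconstruct_kano_survey(cnt), reconstruct_kano_survey(cnt))
  zero <- data.frame(m = 0, o = 0, a = 0, i = 0, q = 0, r = 0)
  expect_error(reconstruct_kano_survey(zero), "at least one respondent")
  uneven <- data.frame(m = c(2, 3), o = 0, a = 0, i = 0, q = 0, r = 0)
  expect_error(reconstruct_kano_survey(uneven), "same total n")
})

test_that("group reconstruction reproduces per-group tallies and sizes", {
  gc <- telenursing_group_counts("residence")
  svy <- reconstruct_kano_groups(gc, covariate = "residence")
  expect_equal(sort(unique(svy$residence)), c("Rural", "Urban"))
  expect_equal(sum(svy$residence == "Rural"), 173)
  expect_equal(sum(svy$residence == "Urban"), 175)
  expect_false(any(duplicated(svy$respondent_id)))
  for (g in c("Rural", "Urban")) {
    back <- kano_counts(svy[svy$residence == g, ])
    want <- gc[gc$group == g, c("attribute_id", "m", "o", "a", "i", "q", "r")]
    expect_equal(
      as.data.frame(back[c("attribute_id", "m", "o", "a", "i", "q", "r")]),
      as.data.frame(want),
      ignore_attr = TRUE
    )
  }
})

test_that("bundled study tables pass their marginal-total integrity checks", {
  expect_equal(nrow(telenursing_attributes()), 15)
  expect_false(any(duplicated(telenursing_attributes()$attribute_id)))
  cnt <- telenursing_counts()
  expect_true(all(cnt$n == 348))
  expect_equal(as.integer(cnt[6, c("m", "o", "a", "i", "q", "r")]), c(105L, 88L, 73L, 73L, 7L, 2L))
  gc5 <- telenursing_group_counts("city")
  yz1 <- gc5[gc5$attribute_id == 1 & gc5$group == "Yangzhou", ]
  expect_equal(as.integer(yz1[c("m", "o", "a", "i", "q", "r")]), c(3L, 13L, 88L, 59L, 6L, 4L))
  expect_true(all(gc5$n[gc5$group == "Yangzhou"] == 173))
  expect_true(all(gc5$n[gc5$group == "Nantong"] == 175))
  gc6 <- telenursing_group_counts("residence")
  expect_true(all(tapply(gc6$n, gc6$group, unique) == c(Rural = 173, Urban = 175)))
  demo <- telenursing_demographics()
  expect_true(all(tapply(demo$n, demo$covariate, sum) == 348))
  # bundled CSV copies agree with the in-code constants
  csv <- readr::read_csv(
    system.file("extdata", "telenursing_counts.csv", package = "kanosurvey"),
    col_types = "iiiiiiii", progress = FALSE
  )
  expect_equal(as.data.frame(csv), as.data.frame(cnt))
})
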