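test_that("EAT-26 scoring follows the published coding in both directions", {
  all_never <- c(rep("Never", 25), "Always")
  expect_identical(score_eat26(all_never), 0L)
  maximal <- c(rep("Always", 25), "Never")
  expect_identical(score_eat26(maximal), 78L)
  expect_identical(score_eat26(maximal, exclude_bn_items = TRUE), 69L)
  # numeric levels 1..6 are accepted and equivalent to labels
  expect_identical(score_eat26(c(rep(6, 25), 1)), 78L)
  # item 26 reverse anchoring
  expect_identical(score_eat26(c(rep("Never", 25), "Sometimes")), 1L)
  expect_error(score_eat26(rep("Never", 25)), "missing item")
  expect_error(score_eat26(c(rep("Nevr", 25), "Never")), "unknown")
  # exclusion can never increase the total
  set.seed(8)
  for (i in 1:25) {
    r <- sample(1:6, 26, replace = TRUE)
    expect_lte(score_eat26(r, exclude_bn_items = TRUE), score_eat26(r))
  }
})

test_that("symptom-group assignment applies the cutoff and tie rule", {
  expect_identical(as.character(assign_symptom_group(28)), "high")
  expect_identical(as.character(assign_symptom_group(6)), "low")
  expect_identical(as.character(assign_symptom_group(20)), "high")
  expect_identical(as.character(assign_symptom_group(20, ties = "low")),
                   "low")
  expect_identical(as.character(assign_symptom_group(19.5)), "low")
  expect_error(assign_symptom_group(-1), "non-negative")
})

test_that("CFC scoring reverses items 3-5 and 9-12 and spans 12-60", {
  hi <- c(5, 5, 1, 1, 1, 5, 5, 5, 1, 1, 1, 1)
  expect_identical(score_cfc(hi), 60L)
  lo <- c(1, 1, 5, 5, 5, 1, 1, 1, 5, 5, 5, 5)
  expect_identical(score_cfc(lo), 12L)
  expect_identical(score_cfc(rep(3, 12)), 36L)
  expect_error(score_cfc(rep(6, 12)), "levels 1..5")
  expect_error(score_cfc(rep(3, 11)), "12 items")
})

test_that("ZTPI future subscale averages keyed items with reversals", {
  key <- default_scoring_keys()$ztpi_future
  full <- setNames(rep(5, 56), 1:56)
  key_norev <- list(items = key$items, reversed = integer(0))
  expect_equal(score_ztpi_future(full, key_norev), 5.0)
  expect_equal(score_ztpi_future(setNames(rep(3, 56), 1:56), key), 3.0)
  # one reversed item among n: mean = ((n-1)*4 + 2)/n
  n <- length(key$items)
  key1 <- list(items = key$items, reversed = key$items[1])
  expect_equal(score_ztpi_future(setNames(rep(4, 56), 1:56), key1),
               ((n - 1) * 4 + 2) / n)
  expect_error(score_ztpi_future(setNames(rep(3, 5), 1:5), key),
               "incomplete")
})

test_that("PFE ratio counts future thoughts over total thoughts", {
  expect_equal(score_pfe(c(rep("future", 4), rep("past", 3),
                           rep("present", 3))), 0.4)
  expect_equal(score_pfe(rep("past", 10)), 0)
  expect_equal(score_pfe(rep("future", 10)), 1)
  expect_error(score_pfe(character(0)), "at least one")
  expect_error(score_pfe(c("future", "maybe")), "past/present/future")
})

test_that("dispositional-negativity instruments score per their keys", {
  expect_identical(score_bdi(rep(0, 21)), 0L)
  expect_identical(score_bdi(rep(3, 21)), 63L)
  key_st <- default_scoring_keys()$stai_t
  # all raw 4: reversed items contribute 1 each
  n_rev <- length(key_st$reversed)
  expect_identical(score_stai_t(rep(4, 20)),
                   as.integer((20 - n_rev) * 4 + n_rev * 1))
  expect_identical(score_stai_t(rep(1, 20)),
                   as.integer((20 - n_rev) * 1 + n_rev * 4))
  dn <- score_dn_instruments(rep(1, 21), rep(2, 20), rep(4, 26))
  expect_identical(dn$bdi_total, 21L)
  expect_equal(dn$atq_na_mean, 4)
  expect_error(score_bdi(rep(4, 21)), "0..3")
})

test_that("battery scoring is permutation-invariant and handles missing instruments", {
  co <- generate_cohort(cohort_spec(n = 12, seed = 21))
  sc1 <- score_battery(co$items)
  shuffled <- co$items[sample.int(nrow(co$items)), ]
  sc2 <- score_battery(shuffled)
  expect_equal(sc1, sc2)
  expect_true(all(sc1$eat26_total >= 0 & sc1$eat26_total <= 78))
  expect_true(all(sc1$cfc_total >= 12 & sc1$cfc_total <= 60))
  # integer-valued where the instrument is a sum
  expect_type(sc1$eat26_total, "integer")
  expect_type(sc1$cfc_total, "integer")
  # a participant missing an instrument scores NA there
  drop_cfc <- co$items[!(co$items$participant_id == 1 &
                           co$items$instrument == "cfc"), ]
  sc3 <- score_battery(drop_cfc)
  expect_true(is.na(sc3$cfc_total[sc3$participant_id == 1]))
  expect_false(anyNA(sc3$cfc_total[sc3$participant_id != 1]))
  expect_error(score_battery(rbind(co$items, co$items[1, ])),
               "duplicate")
})
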