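test_that("per-lesion points follow the bruise/wound size scale with deep bonus", {
  sizes <- size_classes()
  expect_equal(score_lesion("bruise", sizes), c(1L, 2L, 3L, 4L))
  expect_equal(score_lesion("wound", sizes), c(2L, 4L, 6L, 8L))
  expect_equal(score_lesion("wound", sizes, deep = TRUE), c(4L, 6L, 8L, 10L))
  # wounds score exactly twice the bruise points at every size bin
  expect_equal(score_lesion("wound", sizes), 2L * score_lesion("bruise", sizes))
  expect_error(score_lesion("bruise", "lt_half_cm", deep = TRUE), "deep")
  expect_error(score_lesion("wound", "huge"), "size class")
})

test_that("raw sizes in cm map to the documented bins (1.0 cm in the second)", {
  expect_equal(size_class_from_cm(c(0.2, 0.5, 1.0, 1.01, 2.9, 3.0, 7)),
               c("lt_half_cm", "half_to_one_cm", "half_to_one_cm",
                 "one_to_three_cm", "one_to_three_cm", "ge_three_cm",
                 "ge_three_cm"))
  expect_error(size_class_from_cm(-1), "non-negative")
})

test_that("severity categories follow the point rules including the single-lesion override", {
  expect_equal(classify_severity(0, 0), "A")
  expect_equal(classify_severity(c(1, 2), c(1, 2)), c("B", "B"))
  expect_equal(classify_severity(11, 6), "C")
  expect_equal(classify_severity(12, 4), "D")
  expect_equal(classify_severity(8, 8), "D")   # eight points from one lesion
  expect_equal(classify_severity(10, 10), "D") # deep >=3 cm wound, also one lesion
  expect_error(classify_severity(-1, 0), "negative")
  expect_error(classify_severity(3, 5), "single lesion")
  expect_equal(merge_severity(c("A", "B", "C", "D")),
               c("AB", "AB", "CD", "CD"))
})

test_that("worked scoring cases reproduce the published point totals", {
  # one bruise not exceeding 1 cm -> 2 points, mild
  r <- score_horse(lesion_rows("bruise", "half_to_one_cm"))
  expect_equal(r$total_points, 2L); expect_equal(r$category, "B")
  # one bruise exceeding 1 cm -> 3 points, moderate
  r <- score_horse(lesion_rows("bruise", "one_to_three_cm"))
  expect_equal(r$total_points, 3L); expect_equal(r$category, "C")
  # one < 0.5 cm wound and one < 0.5 cm bruise at the bars -> 3 points
  r <- score_horse(lesion_rows(c("wound", "bruise"), "lt_half_cm"))
  expect_equal(r$total_points, 3L); expect_equal(r$category, "C")
  # the cohort maximum: 6+6+8+8+4+4 = 36 points, severe
  r <- score_horse(lesion_rows(
    kind = "wound",
    size_class = c("one_to_three_cm", "one_to_three_cm", "ge_three_cm",
                   "one_to_three_cm", "half_to_one_cm", "half_to_one_cm"),
    deep = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)))
  expect_equal(r$per_lesion_points, c(6L, 6L, 8L, 8L, 4L, 4L))
  expect_equal(r$total_points, 36L)
  expect_equal(r$max_single_lesion_points, 8L)
  expect_equal(r$category, "D")
  # empty list and old lesions
  expect_equal(score_horse(lesion_rows("wound", "lt_half_cm")[0, ])$category, "A")
  expect_equal(score_horse(lesion_rows("wound", "ge_three_cm",
                                       acute = FALSE))$total_points, 0L)
})

test_that("classification agrees with brute-force enumeration of small lesion multisets", {
  types <- tidyr::expand_grid(kind = lesion_kinds(),
                              size_class = size_classes(),
                              deep = c(FALSE, TRUE))
  types <- types[!(types$kind == "bruise" & types$deep), ]
  pts <- score_lesion(types$kind, types$size_class, types$deep)
  k <- nrow(types)
  # all multisets of size 0..3 over the 12 lesion types
  idx_sets <- c(list(integer(0)),
                lapply(seq_len(k), function(i) i),
                unlist(lapply(seq_len(k), function(i)
                  lapply(i:k, function(j) c(i, j))), recursive = FALSE),
                unlist(lapply(seq_len(k), function(i)
                  unlist(lapply(i:k, function(j)
                    lapply(j:k, function(l) c(i, j, l))),
                    recursive = FALSE)), recursive = FALSE))
  for (idx in idx_sets) {
    lesions <- lesion_rows(types$kind[idx], types$size_class[idx],
                           types$deep[idx])
    r <- score_horse(lesions)
    total <- sum(pts[idx]); mx <- if (length(idx)) max(pts[idx]) else 0L
    expect_equal(r$total_points, as.integer(total))
    expect_equal(r$category, classify_severity(total, mx))
    # merged is AB exactly when the total is at most two points
    expect_equal(r$merged == "AB", total <= 2)
  }
})

test_that("scoring is additive and monotone in lesion size", {
  withr::with_seed(7, {
    types <- tidyr::expand_grid(kind = lesion_kinds(),
                                size_class = size_classes(),
                                deep = c(FALSE, TRUE))
    types <- types[!(types$kind == "bruise" & types$deep), ]
    for (rep in 1:25) {
      n <- sample(0:5, 1)
      pick <- types[sample(nrow(types), n, replace = TRUE), ]
      lesions <- lesion_rows(pick$kind, pick$size_class, pick$deep)
      base <- score_horse(lesions)
      extra <- types[sample(nrow(types), 1), ]
      grown <- score_horse(dplyr::bind_rows(
        lesions, lesion_rows(extra$kind, extra$size_class, extra$deep)))
      expect_gte(grown$total_points, base$total_points)
    }
    # enlarging a lesion's size bin never decreases its points
    for (kind in lesion_kinds()) {
      expect_true(all(diff(score_lesion(kind, size_classes())) > 0))
    }
  })
})

test_that("cohort scoring joins lesions on horse_id and defaults to category A", {
  ex <- make_exams(3)
  les <- dplyr::bind_rows(
    lesion_rows("wound", "ge_three_cm", horse_id = "H0001"),
    lesion_rows(c("bruise", "bruise"), "lt_half_cm", horse_id = "H0003"))
  scored <- score_cohort(ex, les)
  expect_equal(scored$total_points, c(8L, 0L, 2L))
  expect_equal(scored$category, c("D", "A", "B"))
  expect_equal(scored$merged, c("CD", "AB", "AB"))
  expect_error(score_cohort(ex, lesion_rows("wound", "lt_half_cm",
                                            horse_id = "H9999")),
               "unknown horse_id")
})

test_that("covariate binning follows the stated age, thickness and jointedness rules", {
  ex <- make_exams(8)
  ex$age_years <- c(3L, 5L, 6L, 9L, 10L, 15L, 4L, 7L)
  ex$bit_thickness_mm <- c(12L, 13L, 14L, 17L, 18L, 22L, 23L, 30L)
  ex$bit_type <- c("snaffle_trotting", "crescendo", "dr_bristol",
                   "straight_plastic", "mullen_mouth_regulator", "nurmos",
                   "other", "other")
  b <- bin_covariates(ex)
  expect_equal(b$age_group, c("y3_5", "y3_5", "y6_9", "y6_9", "y10_15",
                              "y10_15", "y3_5", "y6_9"))
  expect_equal(b$thickness_class, c("thin", "thin", "basic", "basic",
                                    "thick", "thick", "extra_thick",
                                    "extra_thick"))
  expect_equal(b$jointedness, c("jointed", "jointed", "jointed", "unjointed",
                                "unjointed", "unjointed", "jointed", "jointed"))
  expect_true(all(is.na(bin_covariates(ex, other_jointed = NA)$jointedness[7:8])))
  ex$age_years[1] <- 2L
  expect_error(bin_covariates(ex), "age_years")
})
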