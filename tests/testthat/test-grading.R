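test_that("signal-intensity grading follows the printed cut-offs", {
  cases <- list(c(117, 3), c(6, 1), c(45, 2), c(40, 2), c(60, 2),
                c(39, 1), c(61, 3), c(0, 1), c(100, 3))
  for (cs in cases) expect_equal(grade_signal_intensity(cs[1]), cs[2])
  expect_error(grade_signal_intensity(-5), ">= 0")
})

test_that("lumen-narrowing grading follows the printed cut-offs", {
  cases <- list(c(72, 3), c(0, 1), c(58, 2), c(40, 2), c(70, 2),
                c(39, 1), c(71, 3), c(100, 3))
  for (cs in cases) expect_equal(grade_lumen_narrowing(cs[1]), cs[2])
  expect_warning(out <- grade_lumen_narrowing(110), "clamped")
  expect_equal(out, 3L)
  expect_error(grade_lumen_narrowing(-1), ">= 0")
})

test_that("homogeneity grading follows the printed cut-offs, 0.10 scoring 2", {
  cases <- list(c(0.06, 3), c(0.44, 1), c(0.10, 2), c(0.4, 1),
                c(0.09, 3), c(0.39, 2), c(0, 3))
  for (cs in cases) expect_equal(grade_homogeneity(cs[1]), cs[2])
  expect_error(grade_homogeneity(-0.1), ">= 0")
})

test_that("overall score sums the categories and classifies 3-4 / 5-7 / 8-9", {
  expect_equal(overall_grade(3, 2, 3)$overall_score, 8L)
  expect_equal(as.character(overall_grade(3, 2, 3)$overall_class), "good")
  expect_equal(overall_grade(1, 1, 1)$overall_score, 3L)
  expect_equal(as.character(overall_grade(1, 1, 1)$overall_class), "poor")
  expect_equal(overall_grade(2, 2, 2)$overall_score, 6L)
  expect_equal(as.character(overall_grade(2, 2, 2)$overall_class), "intermediate")
  # boundary sums
  expect_equal(as.character(overall_grade(2, 1, 1)$overall_class), "poor")         # 4
  expect_equal(as.character(overall_grade(2, 2, 1)$overall_class), "intermediate") # 5
  expect_equal(as.character(overall_grade(3, 3, 1)$overall_class), "intermediate") # 7
  expect_error(overall_grade(0, 2, 2), "1, 2 or 3")
})

test_that("each grading rule is a monotone step function", {
  set.seed(7)
  si <- sort(runif(200, 0, 130))
  expect_true(all(diff(grade_signal_intensity(si)) >= 0))
  vis <- sort(runif(200, 0, 100))
  expect_true(all(diff(grade_lumen_narrowing(vis)) >= 0))
  hom <- sort(runif(200, 0, 1))
  expect_true(all(diff(grade_homogeneity(hom)) <= 0))
})

test_that("grading a table is deterministic, id-ordered, and handles empty input", {
  tab <- measurements_table2()
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  g <- suppressWarnings(grade_measurements(shuffled))
  expect_equal(g$stent_id, sort(tab$stent_id))
  expect_s3_class(g, "stent_grades")
  expect_true(all(g$overall_score >= 3 & g$overall_score <= 9))
  # class partition is exhaustive and exclusive
  expect_false(anyNA(g$overall_class))

  empty <- grade_measurements(tab[0, ])
  expect_equal(nrow(empty), 0)
  counts <- grade_counts(empty)
  expect_true(all(counts[c("good", "intermediate", "poor")] == 0))

  expect_error(grade_measurements(rbind(tab, tab)), "unique")
  expect_error(grade_measurements(tab["name"]), "lack")
})

test_that("tidy and glance summarise a graded table", {
  g <- suppressWarnings(grade_measurements(measurements_table2()))
  td <- tidy(g)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "stent_grades"))
  gl <- glance(g)
  expect_equal(gl$n_stents, 22L)
  expect_equal(gl$n_truncated, 4L)
})

test_that("stent catalogue fixture matches the published material mix", {
  tab <- stent_table1()
  expect_equal(nrow(tab), 22)
  mats <- table(tab$material)
  expect_equal(unname(mats["nitinol"]), 10L)
  expect_equal(unname(mats["316L"]), 7L)
  expect_equal(unname(mats["tantalum"]), 2L)
  expect_true(all(tab$diameter_mm %in% c(5, 6, 7, 8, 10, 13)))
  specs <- stent_specs_from_table(tab)
  expect_length(specs, 22)
  expect_equal(specs[["Wallgraft Endoprothesis"]]$design, "covered")
  expect_equal(specs[["Palmaz Genesis"]]$design, "slotted_tube")
})
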