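make_cohort_df <- function() {
  data.frame(
    ID = c("a1", "a2", "a3"),
    Sex = c("F", "male", "M"),
    Age_y = c(10.25, 3.5, 17.0),
    Height_cm = c(140, 98, NA),
    Weight_kg = c(38, 15.2, NA),
    BMI = c(NA, NA, 22.5),
    stringsAsFactors = FALSE
  )
}

test_that("cohort files parse row-by-row without aborting on bad rows", {
  path <- write_tmp_csv(make_cohort_df(), "cohort.csv")
  got <- read_cohort(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$sex, c("female", "male", "male"))
  # BMI-only row keeps its supplied BMI
  expect_equal(got$bmi_supplied[3], 22.5)

  bad <- make_cohort_df(); bad$Sex[2] <- "X"
  got2 <- read_cohort(write_tmp_csv(bad, "bad.csv"))
  expect_equal(nrow(got2), 3)
  expect_true(is.na(got2$sex[2]))
  expect_match(got2$qc_flags[2], "invalid_sex")
  expect_equal(got2$qc_flags[1], "")  # other rows still parse clean
})

test_that("missing required columns are fatal", {
  noage <- make_cohort_df(); noage$Age_y <- NULL
  expect_error(read_cohort(write_tmp_csv(noage, "na.csv")), "required")
  nosrc <- make_cohort_df()[, c("ID", "Sex", "Age_y")]
  expect_error(read_cohort(write_tmp_csv(nosrc, "ns.csv")), "BMI")
})

test_that("unit conversions apply the exact printed factors", {
  expect_identical(convert_length_in_to_cm(1), 2.54)
  expect_identical(convert_weight_lb_to_kg(2.20462), 1)
  expect_identical(convert_length_in_to_cm(0), 0)
  expect_identical(convert_weight_lb_to_kg(0), 0)
  # inverse consistency
  x <- c(0.5, 23.7, 180)
  expect_equal(convert_weight_kg_to_lb(convert_weight_lb_to_kg(x)), x,
               tolerance = 1e-9)
  expect_equal(convert_length_cm_to_in(convert_length_in_to_cm(x)), x,
               tolerance = 1e-9)
  expect_error(convert_length_in_to_cm(-1), "non-negative")
  expect_error(convert_weight_lb_to_kg(-1), "non-negative")
})

test_that("height and weight are preferred over a supplied BMI", {
  got <- effective_bmi(100, 16, bmi_supplied = 99)
  expect_equal(got$bmi, 16)
  expect_equal(got$source, "computed")
  got2 <- effective_bmi(NA, NA, bmi_supplied = 22.5)
  expect_equal(got2$bmi, 22.5)
  expect_equal(got2$source, "supplied")
  expect_error(effective_bmi(NA, NA, NA), "neither")
  batch <- effective_bmi(c(100, NA), c(16, NA), c(NA, NA), strict = FALSE)
  expect_equal(batch$source, c("computed", "none"))
})

test_that("replicated IDs flip the data set to longitudinal", {
  expect_equal(detect_mode(c(1, 2, 3)), "cross_sectional")
  expect_equal(detect_mode(c(1, 1, 2)), "longitudinal")
  expect_equal(detect_mode("solo"), "cross_sectional")
  expect_error(detect_mode(character(0)), "empty")
})

test_that("scoring computes the full metric bundle per row", {
  # a subject sitting exactly at the median of the reference
  age <- 8.5
  lms <- interpolate_lms(test_ref, "female", age * 12)
  h <- 130
  w <- lms$M * (h / 100)^2
  coh <- as_cohort(data.frame(ID = "m1", Sex = "F", Age_y = age,
                              Height_cm = h, Weight_kg = w, BMI = NA))
  res <- compute_results(coh, test_ref)
  expect_equal(res$bmi_z, 0, tolerance = 1e-9)
  expect_equal(res$bmi_pct, 50, tolerance = 1e-7)
  expect_equal(as.character(res$weight_status), "healthy weight")

  # a subject constructed at 1.4x the P95 lands in class 3 by the percent
  # arm (nudged a hair inside the class so float division cannot tie-break
  # the inclusive boundary the wrong way)
  p95 <- bmi_at_percentile(95, lms$L, lms$M, lms$S)
  w3 <- 1.4 * p95 * (h / 100)^2 * (1 + 1e-9)
  coh3 <- as_cohort(data.frame(ID = "m3", Sex = "F", Age_y = age,
                               Height_cm = h, Weight_kg = w3, BMI = NA))
  res3 <- compute_results(coh3, test_ref)
  expect_equal(res3$bmi_95, 140, tolerance = 1e-6)
  expect_equal(as.character(res3$weight_status), "severe obesity class 3")
})

test_that("out-of-range and defective rows are flagged, never dropped", {
  coh <- as_cohort(data.frame(
    ID = c("k1", "k2", "k3", "k4"),
    Sex = c("F", "F", "Q", "M"),
    Age_y = c(1.0, 20.0, 9, 9),
    Height_cm = c(80, 170, 140, 140),
    Weight_kg = c(11, 70, 40, 40),
    BMI = NA
  ))
  res <- compute_results(coh, test_ref)
  expect_equal(nrow(res), 4)
  expect_match(res$qc_flags[1], "age_out_of_range")   # 1 y: below window
  expect_match(res$qc_flags[2], "age_out_of_range")   # 20 y: window is [2, 20)
  expect_match(res$qc_flags[3], "invalid_sex")
  expect_true(all(is.na(res$weight_status[1:3])))
  expect_false(is.na(res$weight_status[4]))
})

test_that("conflicting sex for one ID and BMI discrepancies raise flags", {
  coh <- as_cohort(data.frame(
    ID = c("x", "x", "y"),
    Sex = c("F", "M", "F"),
    Age_y = c(9, 10, 9),
    Height_cm = c(135, 140, 135),
    Weight_kg = c(32, 35, 32),
    BMI = c(NA, NA, 19.9)  # computed 17.56 -> discrepancy > 0.1
  ))
  res <- compute_results(coh, test_ref)
  expect_match(res$qc_flags[1], "sex_conflict")
  expect_match(res$qc_flags[2], "sex_conflict")
  expect_match(res$qc_flags[3], "bmi_discrepancy")
  expect_equal(res$bmi_kgm2[3], 32 / 1.35^2)  # discrepancy does not alter value
})

test_that("whole-number ages draw a misclassification warning flag", {
  coh <- as_cohort(data.frame(ID = "w", Sex = "M", Age_y = 7,
                              Height_cm = 122, Weight_kg = 24, BMI = NA))
  expect_match(coh$qc_flags, "whole_number_age")
  coh2 <- as_cohort(data.frame(ID = "w", Sex = "M", Age_y = 7.25,
                               Height_cm = 122, Weight_kg = 24, BMI = NA))
  expect_equal(coh2$qc_flags, "")
})

test_that("results file keeps inputs, appends outputs, and round-trips", {
  s <- synth_cohort(12, test_ref, seed = 21)
  res <- compute_results(as_cohort(s$cohort), test_ref)
  dir <- withr::local_tempdir()
  path <- write_results(res, dir = dir)
  expect_equal(basename(path), "BMI_Results.csv")
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), nrow(res))
  expect_equal(names(back)[1:6],
               c("ID", "Sex", "Age_y", "Height_cm", "Weight_kg", "BMI"))
  expect_true(all(c("BMI_kgm2", "BMI_pct", "BMI_z", "BMI_95",
                    "Weight_status") %in% names(back)))
  expect_true(all(back$Weight_status %in% weight_status_levels))
  # written precision: 2 decimals for BMI-scale values, 4 for z
  expect_equal(back$BMI_kgm2, round(res$bmi_kgm2, 2))
  expect_equal(back$BMI_z, round(res$bmi_z, 4))

  empty <- write_results(res[0, ], path = file.path(dir, "empty.csv"))
  expect_equal(nrow(utils::read.csv(empty)), 0)
})
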