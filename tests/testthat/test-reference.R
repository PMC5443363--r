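test_that("a well-formed reference file loads, sorted, with both sexes", {
  path <- write_tmp_csv(as.data.frame(test_ref)[sample(nrow(test_ref)), ],
                        "ref.csv")
  got <- load_lms_reference(path)
  expect_s3_class(got, "lms_reference")
  expect_setequal(unique(got$sex), c("female", "male"))
  expect_equal(as.data.frame(got), as.data.frame(test_ref),
               ignore_attr = TRUE)
  for (sx in c("female", "male")) {
    expect_true(all(diff(got$age_months[got$sex == sx]) > 0))
  }
})

test_that("invalid reference tables are rejected with row diagnostics", {
  df <- as.data.frame(test_ref)
  bad <- df; bad$M[7] <- -1
  expect_error(load_lms_reference(write_tmp_csv(bad, "m.csv")), "7")
  onesex <- df[df$sex == "female", ]
  expect_error(load_lms_reference(write_tmp_csv(onesex, "f.csv")),
               "sex stratum absent")
  dup <- rbind(df, df[1, ])
  expect_error(load_lms_reference(write_tmp_csv(dup, "d.csv")), "duplicate")
  nocol <- df; names(nocol)[names(nocol) == "S"] <- "spread"
  expect_error(load_lms_reference(write_tmp_csv(nocol, "c.csv")),
               "missing a column")
  nonnum <- df; nonnum$L <- as.character(nonnum$L); nonnum$L[3] <- "x"
  expect_error(load_lms_reference(write_tmp_csv(nonnum, "n.csv")),
               "non-numeric")
  toolow <- df; toolow$age_months[df$sex == "female"][1] <- 10
  expect_error(load_lms_reference(write_tmp_csv(toolow, "a.csv")),
               "24")
  expect_error(load_lms_reference("no/such/file.csv"), "not found")
})

test_that("custom column names load through col_map", {
  df <- as.data.frame(test_ref)
  names(df) <- c("gndr", "agemos_x", "lambda_x", "mu_x", "sigma_x")
  got <- load_lms_reference(write_tmp_csv(df, "map.csv"),
                            col_map = c(sex = "gndr", age_months = "agemos_x",
                                        L = "lambda_x", M = "mu_x",
                                        S = "sigma_x"))
  expect_equal(got$M, test_ref$M)
})

test_that("interpolation is exact at knots, linear between, continuous", {
  sub <- tiny_ref[tiny_ref$sex == "female", ]
  at_knot <- interpolate_lms(tiny_ref, "female", 120)
  expect_equal(unlist(at_knot), c(L = -1.5, M = 17.5, S = 0.110))
  mid <- interpolate_lms(tiny_ref, "F", (24 + 120) / 2)
  expect_equal(mid$M, (16.0 + 17.5) / 2)
  expect_equal(mid$L, (-1.0 + -1.5) / 2)
  expect_equal(mid$S, (0.090 + 0.110) / 2)
  # continuity across every interior knot
  for (knot in c(120)) {
    lo <- interpolate_lms(tiny_ref, "female", knot - 1e-9)
    hi <- interpolate_lms(tiny_ref, "female", knot + 1e-9)
    expect_equal(unlist(lo), unlist(hi), tolerance = 1e-6)
  }
  expect_error(interpolate_lms(tiny_ref, "female", 10), "range")
  expect_error(interpolate_lms(tiny_ref, "X", 120), "sex code")
})

test_that("default curve set has the four standard plus two severe curves", {
  cs <- build_curves(test_ref, "female")
  expect_named(cs$curves,
               c("P5", "P50", "P85", "P95", "120% of P95", "140% of P95"))
  expect_true(all(lengths(cs$curves) == length(cs$age_months)))
  # P50 is the median M at every grid age
  lms <- interpolate_lms(test_ref, "female", cs$age_months)
  expect_equal(cs$curves$P50, lms$M, tolerance = 1e-12)
  # severe curves are exact multiples of P95
  expect_equal(cs$curves[["120% of P95"]], 1.2 * cs$curves$P95)
  expect_equal(cs$curves[["140% of P95"]], 1.4 * cs$curves$P95)
  # percentile ordering is pointwise monotone
  expect_true(all(cs$curves$P5 <= cs$curves$P50))
  expect_true(all(cs$curves$P50 <= cs$curves$P85))
  expect_true(all(cs$curves$P85 <= cs$curves$P95))
  expect_error(build_curves(test_ref, "female", percentiles = c(0, 50)),
               "between")
})

test_that("extra percentile curves stay pointwise ordered", {
  pcts <- c(3, 10, 25, 75, 90, 97, 99)
  cs <- build_curves(test_ref, "male", percentiles = pcts,
                     include_severe = FALSE, age_step = 2)
  mat <- do.call(cbind, cs$curves)
  expect_equal(ncol(mat), length(pcts))
  expect_true(all(apply(mat, 1, function(r) all(diff(r) > 0))))
})

test_that("curves from the LMS table match an independently supplied curve table", {
  # "supplied" table evaluated straight from the knot parameters, no
  # interpolation path involved
  knots <- as.data.frame(test_ref)
  knots <- knots[knots$age_months <= 240 &
                   knots$age_months %% 0.5 == 0, ]
  wide <- data.frame(sex = knots$sex, age_months = knots$age_months)
  for (p in c(5, 50, 85, 95)) {
    wide[[paste0("P", p)]] <- bmi_at_percentile(p, knots$L, knots$M, knots$S)
  }
  loaded <- read_curve_table(write_tmp_csv(wide, "curves.csv"))
  built <- build_curves(test_ref, "female", include_severe = FALSE)
  expect_equal(loaded$female$age_months, built$age_months)
  for (lbl in names(built$curves)) {
    expect_equal(loaded$female$curves[[lbl]], built$curves[[lbl]],
                 tolerance = 1e-8)
  }
})
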