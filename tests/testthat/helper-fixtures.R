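# shared synthetic LMS reference; deterministic, built once per test run
test_ref <- synth_reference()

# write the reference (or any data.frame) to a temp csv, returning the path
write_tmp_csv <- function(df, name = "tmp.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# a tiny 3-knot-per-sex reference with hand-set values for knot arithmetic
tiny_ref <- new_lms_reference(data.frame(
  sex = rep(c("female", "male"), each = 3),
  age_months = rep(c(24, 120, 240), 2),
  L = c(-1.0, -1.5, -2.0, -0.8, -1.2, -1.6),
  M = c(16.0, 17.5, 22.0, 16.4, 17.2, 21.5),
  S = c(0.090, 0.110, 0.140, 0.088, 0.105, 0.135)
))

# severity rank helper for monotonicity checks
status_rank <- function(s) match(as.character(s), weight_status_levels)
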