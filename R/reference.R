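#' Load and validate an LMS reference table
#'
#' Reads a per-sex table of age-varying LMS parameters (Box-Cox power L,
#' median M, coefficient of variation S) of the kind distributed with the
#' CDC 2000 growth charts, and validates it for use as a BMI-for-age
#' reference. The package does not ship reference values; see
#' [synth_reference()] for a synthetic stand-in used by the tests and
#' examples.
#'
#' @param path CSV or spreadsheet (`.xlsx`/`.xls`) file. Column headers are
#'   matched case-insensitively; alternative names can be supplied through
#'   `col_map`.
#' @param col_map Optional named character vector mapping the canonical names
#'   `sex`, `age_months`, `L`, `M`, `S` to the file's header names.
#' @return An object of class `lms_reference`: a data.frame with columns
#'   `sex` (`"female"`/`"male"`), `age_months`, `L`, `M`, `S`, sorted by sex
#'   then age.
#' @details Validation enforces: numeric parameters; `M > 0` and `S > 0`;
#'   ages within \[24, 240.5\] months; within each sex a strictly increasing,
#'   duplicate-free age grid starting at 24 months and reaching at least 240
#'   months (so the full 2 to <20 year window is covered); both sexes
#'   present. Violations are reported with row numbers.
#' @export
load_lms_reference <- function(path, col_map = NULL) {
  df <- read_table_any(path)
  canon <- list(
    sex        = c("sex", "gender"),
    age_months = c("age_months", "agemos", "age", "agemonths", "age_m"),
    L          = c("l", "lambda"),
    M          = c("m", "mu", "median"),
    S          = c("s", "sigma", "cv")
  )
  cols <- character(0)
  for (nm in names(canon)) {
    aliases <- if (!is.null(col_map) && nm %in% names(col_map)) {
      col_map[[nm]]
    } else {
      canon[[nm]]
    }
    hit <- match_header(df, aliases)
    if (is.na(hit)) stop("reference file is missing a column for ", sQuote(nm),
                         call. = FALSE)
    cols[nm] <- hit
  }
  out <- suppressWarnings(data.frame(
    sex        = normalize_sex(df[[cols["sex"]]], strict = FALSE),
    age_months = as.numeric(df[[cols["age_months"]]]),
    L          = as.numeric(df[[cols["L"]]]),
    M          = as.numeric(df[[cols["M"]]]),
    S          = as.numeric(df[[cols["S"]]]),
    stringsAsFactors = FALSE
  ))
  new_lms_reference(out)
}

#' Construct an `lms_reference` from a data.frame
#'
#' @param df Data frame with columns `sex`, `age_months`, `L`, `M`, `S`.
#' @return Validated `lms_reference` object sorted by sex then age.
#' @export
new_lms_reference <- function(df) {
  req <- c("sex", "age_months", "L", "M", "S")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[req]
  bad_sex <- which(is.na(normalize_sex(df$sex, strict = FALSE)))
  if (length(bad_sex)) {
    stop("invalid sex code in reference row(s): ",
         paste(utils::head(bad_sex, 5), collapse = ", "), call. = FALSE)
  }
  df$sex <- normalize_sex(df$sex, strict = FALSE)
  num_bad <- which(!stats::complete.cases(df) |
                     !is.finite(df$age_months) | !is.finite(df$L) |
                     !is.finite(df$M) | !is.finite(df$S))
  if (length(num_bad)) {
    stop("non-numeric or missing parameter in reference row(s): ",
         paste(utils::head(num_bad, 5), collapse = ", "), call. = FALSE)
  }
  bad_pos <- which(df$M <= 0 | df$S <= 0)
  if (length(bad_pos)) {
    stop("M and S must be positive; violated in reference row(s): ",
         paste(utils::head(bad_pos, 5), collapse = ", "), call. = FALSE)
  }
  bad_age <- which(df$age_months < 24 | df$age_months > 240.5)
  if (length(bad_age)) {
    stop("age_months outside [24, 240.5] in reference row(s): ",
         paste(utils::head(bad_age, 5), collapse = ", "), call. = FALSE)
  }
  for (sx in c("female", "male")) {
    sub <- df[df$sex == sx, ]
    if (nrow(sub) == 0) stop("sex stratum absent: ", sx, call. = FALSE)
    if (anyDuplicated(sub$age_months)) {
      stop("duplicate (sex, age) pair in the ", sx, " stratum", call. = FALSE)
    }
    ages <- sort(sub$age_months)
    if (min(ages) > 24 || max(ages) < 240) {
      stop("the ", sx, " age grid must span 24 through at least 240 months; ",
           "got [", min(ages), ", ", max(ages), "]", call. = FALSE)
    }
  }
  df <- df[order(df$sex, df$age_months), ]
  rownames(df) <- NULL
  structure(df, class = c("lms_reference", "data.frame"))
}

#' @export
print.lms_reference <- function(x, ...) {
  cat("<lms_reference>\n")
  for (sx in unique(x$sex)) {
    a <- x$age_months[x$sex == sx]
    cat(sprintf("  %-6s %4d knots, ages %.1f-%.1f months\n",
                sx, length(a), min(a), max(a)))
  }
  invisible(x)
}

#' Interpolate LMS parameters at an age
#'
#' Linear interpolation of L, M and S independently in age; exact at the
#' reference grid's knots.
#'
#' @param reference An [`lms_reference`][load_lms_reference].
#' @param sex `"female"` or `"male"` (or any accepted code, see
#'   [normalize_sex()]).
#' @param age_months Age(s) in months; must lie within the sex's grid range.
#' @return A data.frame with columns `L`, `M`, `S`, one row per queried age.
#' @export
interpolate_lms <- function(reference, sex, age_months) {
  stopifnot(inherits(reference, "lms_reference"))
  sex <- normalize_sex(sex)
  if (length(sex) != 1) stop("sex must be a single code", call. = FALSE)
  sub <- reference[reference$sex == sex, ]
  rng <- range(sub$age_months)
  if (any(!is.finite(age_months) | age_months < rng[1] | age_months > rng[2])) {
    stop(sprintf("age_months outside the supported range [%.1f, %.1f] for %s",
                 rng[1], rng[2], sex), call. = FALSE)
  }
  data.frame(
    L = stats::approx(sub$age_months, sub$L, xout = age_months)$y,
    M = stats::approx(sub$age_months, sub$M, xout = age_months)$y,
    S = stats::approx(sub$age_months, sub$S, xout = age_months)$y
  )
}

#' Build percentile and severe-obesity curves for charting
#'
#' Evaluates BMI at each requested percentile over an age grid, and, when
#' `include_severe = TRUE`, adds the two severe-obesity reference curves:
#' 120% of the 95th percentile (the obese class 2 cut point) and 140% of the
#' 95th percentile (the class 3 cut point).
#'
#' @inheritParams interpolate_lms
#' @param percentiles Percentile values in (0, 100). Default is the four
#'   standard chart curves: 5, 50, 85, 95.
#' @param include_severe Add the 1.2x and 1.4x multiples of the P95 curve
#'   (computed even if 95 is not among `percentiles`).
#' @param age_step Grid step in months (default 0.5).
#' @return A `bmi_curveset`: list with `sex`, `age_months` (the grid) and
#'   `curves`, a named list of BMI vectors with labels `"P5"`, `"P50"`, ...,
#'   `"120% of P95"`, `"140% of P95"`.
#' @export
build_curves <- function(reference, sex, percentiles = c(5, 50, 85, 95),
                         include_severe = TRUE, age_step = 0.5) {
  stopifnot(inherits(reference, "lms_reference"), age_step > 0)
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie strictly between 0 and 100", call. = FALSE)
  }
  sex <- normalize_sex(sex)
  sub <- reference[reference$sex == sex, ]
  hi <- min(max(sub$age_months), .age_window_months[2])
  grid <- seq(.age_window_months[1], hi, by = age_step)
  lms <- interpolate_lms(reference, sex, grid)
  curves <- lapply(sort(percentiles), function(p) {
    bmi_at_percentile(p, lms$L, lms$M, lms$S)
  })
  names(curves) <- paste0("P", format(sort(percentiles), trim = TRUE))
  if (include_severe) {
    p95 <- bmi_at_percentile(95, lms$L, lms$M, lms$S)
    curves[["120% of P95"]] <- 1.2 * p95
    curves[["140% of P95"]] <- 1.4 * p95
  }
  structure(list(sex = sex, age_months = grid, curves = curves),
            class = "bmi_curveset")
}

#' @export
print.bmi_curveset <- function(x, ...) {
  cat(sprintf("<bmi_curveset> %s, %d grid ages (%.0f-%.0f months), curves: %s\n",
              x$sex, length(x$age_months), min(x$age_months),
              max(x$age_months), paste(names(x$curves), collapse = ", ")))
  invisible(x)
}

#' @describeIn build_curves Long-format data.frame of a curve set
#'   (columns `sex`, `age_months`, `age_y`, `curve`, `bmi`), convenient for
#'   plotting or writing to disk.
#' @param x A `bmi_curveset`.
#' @param ... Unused.
#' @export
as.data.frame.bmi_curveset <- function(x, ...) {
  do.call(rbind, lapply(names(x$curves), function(lbl) {
    data.frame(sex = x$sex, age_months = x$age_months,
               age_y = x$age_months / 12, curve = lbl,
               bmi = x$curves[[lbl]], stringsAsFactors = FALSE)
  }))
}

#' Read a precomputed percentile-curve table
#'
#' Accepts a CSV/spreadsheet with columns `sex`, `age_months` and one column
#' per curve label (e.g. `P5`, `P50`, `P85`, `P95`), the same role as a
#' published percentile-curve workbook, and returns one `bmi_curveset` per
#' sex. Useful for cross-checking curves built from an LMS table against an
#' independently supplied set.
#'
#' @param path File path.
#' @return Named list of `bmi_curveset` objects, one per sex present.
#' @export
read_curve_table <- function(path) {
  df <- read_table_any(path)
  sex_col <- match_header(df, c("sex", "gender"))
  age_col <- match_header(df, c("age_months", "agemos", "age"))
  if (is.na(sex_col) || is.na(age_col)) {
    stop("curve table needs 'sex' and 'age_months' columns", call. = FALSE)
  }
  curve_cols <- setdiff(names(df), c(sex_col, age_col))
  if (!length(curve_cols)) stop("curve table has no curve columns", call. = FALSE)
  sexes <- normalize_sex(df[[sex_col]], strict = FALSE)
  out <- lapply(stats::setNames(nm = sort(unique(sexes))), function(sx) {
    sub <- df[sexes == sx, , drop = FALSE]
    sub <- sub[order(as.numeric(sub[[age_col]])), , drop = FALSE]
    structure(list(
      sex = sx,
      age_months = as.numeric(sub[[age_col]]),
      curves = lapply(stats::setNames(nm = curve_cols),
                      function(cc) as.numeric(sub[[cc]]))
    ), class = "bmi_curveset")
  })
  out
}
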