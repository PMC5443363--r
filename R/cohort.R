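#' Read an investigator cohort file
#'
#' Accepts CSV or spreadsheet (`.xlsx`/`.xls`) with the input schema:
#' `ID`, `Sex` (F, M, female, or male), `Age_y` (years, decimals encouraged),
#' `Height_cm`, `Weight_kg`, and optionally `BMI` (needed only when height or
#' weight is not provided). Header matching is case-insensitive. Malformed
#' rows are flagged, not fatal: the batch always parses.
#'
#' @param path Input file.
#' @return Data frame with columns `id`, `sex` (normalised, `NA` if
#'   unrecognised), `sex_raw`, `age_y`, `height_cm`, `weight_kg`,
#'   `bmi_supplied`, `qc_flags` (semicolon-separated row diagnostics, `""`
#'   when clean).
#' @export
read_cohort <- function(path) {
  as_cohort(read_table_any(path))
}

#' Normalise an in-memory cohort table
#'
#' Applies [read_cohort()]'s header matching, sex parsing and row-level QC
#' flagging to a data.frame that is already in memory (e.g. the `cohort`
#' element of [synth_cohort()]).
#'
#' @param df Data frame with the input schema's columns.
#' @return Same shape as [read_cohort()]'s result.
#' @export
as_cohort <- function(df) {
  id_col <- match_header(df, c("id", "subject", "subject_id"))
  sex_col <- match_header(df, c("sex", "gender"))
  age_col <- match_header(df, c("age_y", "age", "age_years"))
  ht_col <- match_header(df, c("height_cm", "height"))
  wt_col <- match_header(df, c("weight_kg", "weight"))
  bmi_col <- match_header(df, c("bmi", "bmi_kgm2", "bmi_supplied"))
  for (nm in c(id_col, sex_col, age_col)) {
    if (is.na(nm)) stop("cohort file is missing a required column ",
                        "(need ID, Sex, Age_y)", call. = FALSE)
  }
  if (is.na(ht_col) && is.na(wt_col) && is.na(bmi_col)) {
    stop("cohort file needs Height_cm and Weight_kg columns, or a BMI column",
         call. = FALSE)
  }
  num <- function(col) {
    if (is.na(col)) return(rep(NA_real_, nrow(df)))
    suppressWarnings(as.numeric(df[[col]]))
  }
  out <- data.frame(
    id = as.character(df[[id_col]]),
    sex = normalize_sex(df[[sex_col]], strict = FALSE),
    sex_raw = as.character(df[[sex_col]]),
    age_y = num(age_col),
    height_cm = num(ht_col),
    weight_kg = num(wt_col),
    bmi_supplied = num(bmi_col),
    stringsAsFactors = FALSE
  )
  flags <- vector("list", nrow(out))
  add_flag <- function(which, flag) {
    for (i in which(which)) flags[[i]] <<- c(flags[[i]], flag)
  }
  add_flag(is.na(out$sex), "invalid_sex")
  add_flag(is.na(out$age_y), "missing_age")
  add_flag(!is.na(out$age_y) & out$age_y == round(out$age_y),
           "whole_number_age")
  no_hw <- is.na(out$height_cm) | is.na(out$weight_kg)
  add_flag(no_hw & is.na(out$bmi_supplied), "no_bmi_source")
  # duplicate id reported with conflicting sex makes the pair unusable
  sex_tab <- tapply(out$sex, out$id, function(s) length(unique(stats::na.omit(s))))
  conflict_ids <- names(sex_tab)[!is.na(sex_tab) & sex_tab > 1]
  add_flag(out$id %in% conflict_ids, "sex_conflict")
  out$qc_flags <- vapply(flags, function(f) paste(f, collapse = ";"), "")
  out
}

#' English-to-metric unit conversions
#'
#' Height and weight must reach the scoring pipeline in metric units; these
#' apply the exact conversion factors: height (cm) = height (inches) * 2.54
#' and weight (kg) = weight (lbs) / 2.20462.
#'
#' @param inches,lbs,cm,kg Non-negative measurements.
#' @return Converted value(s).
#' @export
convert_length_in_to_cm <- function(inches) {
  stopifnot(is.numeric(inches))
  if (any(inches < 0, na.rm = TRUE)) stop("length must be non-negative", call. = FALSE)
  inches * 2.54
}

#' @rdname convert_length_in_to_cm
#' @export
convert_weight_lb_to_kg <- function(lbs) {
  stopifnot(is.numeric(lbs))
  if (any(lbs < 0, na.rm = TRUE)) stop("weight must be non-negative", call. = FALSE)
  lbs / 2.20462
}

#' @rdname convert_length_in_to_cm
#' @export
convert_length_cm_to_in <- function(cm) {
  stopifnot(is.numeric(cm))
  if (any(cm < 0, na.rm = TRUE)) stop("length must be non-negative", call. = FALSE)
  cm / 2.54
}

#' @rdname convert_length_in_to_cm
#' @export
convert_weight_kg_to_lb <- function(kg) {
  stopifnot(is.numeric(kg))
  if (any(kg < 0, na.rm = TRUE)) stop("weight must be non-negative", call. = FALSE)
  kg * 2.20462
}

#' Effective BMI for a subject row
#'
#' Height and weight are used preferentially to compute BMI; an
#' investigator-supplied BMI is used only when height or weight is absent.
#'
#' @param height_cm,weight_kg,bmi_supplied Vectors from a cohort table
#'   (`NA` = absent).
#' @param strict Error when a row has neither source (default). With
#'   `strict = FALSE` such rows return `NA` with source `"none"`, for batch
#'   use.
#' @return Data frame with `bmi` and `source` (`"computed"`, `"supplied"`, or
#'   `"none"`).
#' @export
effective_bmi <- function(height_cm, weight_kg, bmi_supplied = NA_real_,
                          strict = TRUE) {
  n <- max(length(height_cm), length(weight_kg), length(bmi_supplied))
  height_cm <- rep_len(as.numeric(height_cm), n)
  weight_kg <- rep_len(as.numeric(weight_kg), n)
  bmi_supplied <- rep_len(as.numeric(bmi_supplied), n)
  have_hw <- !is.na(height_cm) & !is.na(weight_kg)
  bmi <- rep(NA_real_, n)
  source <- rep("none", n)
  bmi[have_hw] <- bmi_from_hw(height_cm[have_hw], weight_kg[have_hw])
  source[have_hw] <- "computed"
  use_sup <- !have_hw & !is.na(bmi_supplied)
  bmi[use_sup] <- bmi_supplied[use_sup]
  source[use_sup] <- "supplied"
  if (strict && any(source == "none")) {
    stop("row(s) with neither height/weight nor supplied BMI: ",
         paste(utils::head(which(source == "none"), 5), collapse = ", "),
         call. = FALSE)
  }
  data.frame(bmi = bmi, source = source, stringsAsFactors = FALSE)
}

#' Detect cross-sectional vs longitudinal data
#'
#' A data set is treated as longitudinal when any participant ID is
#' replicated (repeat visits); otherwise cross-sectional.
#'
#' @param ids Vector of participant IDs (or a cohort data.frame with an `id`
#'   column).
#' @return `"longitudinal"` or `"cross_sectional"`.
#' @export
detect_mode <- function(ids) {
  if (is.data.frame(ids)) ids <- ids$id
  if (length(ids) == 0) stop("empty cohort", call. = FALSE)
  if (anyDuplicated(ids)) "longitudinal" else "cross_sectional"
}

#' Score a cohort against an LMS reference
#'
#' Per row: resolve the effective BMI, interpolate the reference at
#' `age_y * 12` months, compute z-score, percentile, the 95th-percentile BMI
#' and percent of it, and classify weight status. Rows outside the supported
#' 2 to <20 year window, with unrecognised sex, or with no BMI source are
#' flagged and carried through with empty computed fields rather than
#' aborting the batch. A supplied BMI disagreeing with the height/weight BMI
#' by more than 0.1 kg/m^2 is flagged (`bmi_discrepancy`) without altering
#' the computed value.
#'
#' @param cohort Data frame from [read_cohort()] (or with the same columns).
#' @param reference An [`lms_reference`][load_lms_reference].
#' @return Data frame: the cohort columns plus `bmi_kgm2`, `bmi_pct`,
#'   `bmi_z`, `bmi_95`, `weight_status`, `bmi_source`, `qc_flags`. Row count
#'   always equals the input row count.
#' @export
compute_results <- function(cohort, reference) {
  stopifnot(inherits(reference, "lms_reference"))
  if (!"qc_flags" %in% names(cohort)) cohort$qc_flags <- ""
  if (!"bmi_supplied" %in% names(cohort)) cohort$bmi_supplied <- NA_real_
  n <- nrow(cohort)
  eb <- effective_bmi(cohort$height_cm, cohort$weight_kg,
                      cohort$bmi_supplied, strict = FALSE)
  res <- cohort
  res$bmi_kgm2 <- eb$bmi
  res$bmi_source <- eb$source
  res$bmi_z <- res$bmi_pct <- res$bmi_95 <- rep(NA_real_, n)
  res$weight_status <- factor(rep(NA_character_, n),
                              levels = weight_status_levels)

  add_flag <- function(i, flag) {
    cur <- res$qc_flags[i]
    res$qc_flags[i] <<- ifelse(cur == "", flag, paste(cur, flag, sep = ";"))
  }
  age_m <- res$age_y * 12
  out_of_range <- is.na(age_m) | age_m < .age_window_months[1] |
    age_m >= .age_window_months[2]
  newly <- out_of_range & !is.na(res$age_y) &
    !grepl("age_out_of_range", res$qc_flags)
  if (any(newly)) add_flag(which(newly), "age_out_of_range")

  disagree <- eb$source == "computed" & !is.na(cohort$bmi_supplied) &
    abs(eb$bmi - cohort$bmi_supplied) > 0.1
  if (any(disagree)) add_flag(which(disagree), "bmi_discrepancy")

  usable <- !out_of_range & !is.na(res$sex) & !is.na(eb$bmi)
  for (sx in c("female", "male")) {
    idx <- which(usable & res$sex == sx)
    if (!length(idx)) next
    lms <- interpolate_lms(reference, sx, age_m[idx])
    p95 <- bmi_at_percentile(95, lms$L, lms$M, lms$S)
    res$bmi_z[idx] <- zscore_from_bmi(res$bmi_kgm2[idx], lms$L, lms$M, lms$S)
    res$bmi_pct[idx] <- percentile_from_z(res$bmi_z[idx])
    res$bmi_95[idx] <- pct_of_p95(res$bmi_kgm2[idx], p95)
  }
  res$weight_status <- classify_weight_status(res$bmi_kgm2, res$bmi_pct,
                                              res$bmi_95)
  res
}

#' Write the results file
#'
#' Writes a CSV (default name `BMI_Results.csv`) with the input columns
#' followed by the computed columns in the standard output order:
#' `BMI_kgm2`, `BMI_pct`, `BMI_z`, `BMI_95`, `Weight_status`, plus
#' `QC_flags`. Display rounding: BMI, percentile and percent-of-P95 to 2
#' decimals, z-score to 4; full precision is retained in the in-memory
#' results.
#'
#' @param results Data frame from [compute_results()].
#' @param path Output file; defaults to `BMI_Results.csv` in `dir`.
#' @param dir Directory used when `path` is not given.
#' @return The path written, invisibly.
#' @export
write_results <- function(results, path = NULL, dir = ".") {
  if (is.null(path)) path <- file.path(dir, "BMI_Results.csv")
  out <- data.frame(
    ID = results$id,
    Sex = results$sex_raw %||% results$sex,
    Age_y = results$age_y,
    Height_cm = results$height_cm,
    Weight_kg = results$weight_kg,
    BMI = results$bmi_supplied,
    BMI_kgm2 = round(results$bmi_kgm2, 2),
    BMI_pct = round(results$bmi_pct, 2),
    BMI_z = round(results$bmi_z, 4),
    BMI_95 = round(results$bmi_95, 2),
    Weight_status = as.character(results$weight_status),
    QC_flags = results$qc_flags,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
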