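#' The six youth weight-status categories
#'
#' Ordered from least to most severe. These exact strings appear in the
#' `Weight_status` column of the results file.
#' @export
weight_status_levels <- c(
  "underweight", "healthy weight", "overweight",
  "obese class 1", "severe obesity class 2", "severe obesity class 3"
)

#' Classify youth weight status
#'
#' Assigns exactly one of six mutually exclusive categories from a subject's
#' BMI, BMI-for-age percentile, and BMI as a percent of the sex/age-specific
#' 95th percentile:
#'
#' * underweight: percentile < 5
#' * healthy weight: 5 to < 85
#' * overweight: 85 to < 95
#' * obese class 1: percentile >= 95 and below the class 2 thresholds
#' * severe obesity class 2: 120 to < 140 percent of the 95th percentile
#'   **or** BMI 35.0 to < 40.0 kg/m^2
#' * severe obesity class 3: >= 140 percent of the 95th percentile **or**
#'   BMI >= 40.0 kg/m^2
#'
#' The two severe classes use dual (OR) criteria, so categories are
#' evaluated from most to least severe; this is the only order under which
#' the OR-shaped definitions stay mutually exclusive (e.g. BMI 36 with
#' percent-of-P95 118 is class 2 via the absolute-BMI arm even though the
#' percentile arm alone would say class 1). Lower bounds are inclusive,
#' upper bounds exclusive. `bmi_pct` and `bmi_95` are trusted as given and
#' not cross-checked against each other.
#'
#' @param bmi BMI in kg/m^2, positive.
#' @param bmi_pct BMI-for-age percentile in (0, 100).
#' @param bmi_95 BMI as a percent of the 95th percentile, positive.
#' @return Factor with levels [weight_status_levels]. Vectorised; `NA`
#'   inputs yield `NA` (so flagged rows pass through untouched).
#' @export
classify_weight_status <- function(bmi, bmi_pct, bmi_95) {
  n <- max(length(bmi), length(bmi_pct), length(bmi_95))
  bmi <- rep_len(as.numeric(bmi), n)
  bmi_pct <- rep_len(as.numeric(bmi_pct), n)
  bmi_95 <- rep_len(as.numeric(bmi_95), n)
  ok <- !is.na(bmi) & !is.na(bmi_pct) & !is.na(bmi_95)
  if (any(bmi[ok] <= 0 | bmi_95[ok] <= 0)) {
    stop("bmi and bmi_95 must be positive", call. = FALSE)
  }
  if (any(bmi_pct[ok] <= 0 | bmi_pct[ok] >= 100)) {
    stop("bmi_pct must lie strictly between 0 and 100", call. = FALSE)
  }
  out <- rep(NA_character_, n)
  out[ok] <- ifelse(
    bmi_95[ok] >= 140 | bmi[ok] >= 40, "severe obesity class 3",
    ifelse(bmi_95[ok] >= 120 | bmi[ok] >= 35, "severe obesity class 2",
    ifelse(bmi_pct[ok] >= 95, "obese class 1",
    ifelse(bmi_pct[ok] >= 85, "overweight",
    ifelse(bmi_pct[ok] >= 5, "healthy weight", "underweight")))))
  factor(out, levels = weight_status_levels)
}

#' Prevalence summary of weight-status categories
#'
#' Counts and proportions per category, plus the two aggregates an
#' investigator needs because the classes are mutually exclusive: obesity
#' (classes 1 + 2 + 3) and severe obesity (classes 2 + 3).
#'
#' @param statuses Factor or character vector of weight statuses (levels of
#'   [weight_status_levels]); `NA` entries (unclassified rows) are dropped
#'   from the denominator.
#' @return List with `categories` (data.frame: `status`, `n`, `proportion`,
#'   proportions summing to 1) and `aggregates` (data.frame: `group`, `n`,
#'   `proportion` for obesity and severe obesity).
#' @export
prevalence_summary <- function(statuses) {
  statuses <- factor(statuses, levels = weight_status_levels)
  statuses <- statuses[!is.na(statuses)]
  if (length(statuses) == 0) {
    stop("no classified subjects to summarise", call. = FALSE)
  }
  n <- as.vector(table(statuses))
  total <- length(statuses)
  categories <- data.frame(status = weight_status_levels, n = n,
                           proportion = n / total, stringsAsFactors = FALSE)
  ob <- sum(n[4:6])
  sev <- sum(n[5:6])
  aggregates <- data.frame(
    group = c("obesity (classes 1-3)", "severe obesity (classes 2-3)"),
    n = c(ob, sev),
    proportion = c(ob, sev) / total,
    stringsAsFactors = FALSE
  )
  list(categories = categories, aggregates = aggregates)
}
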