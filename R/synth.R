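#' Synthetic LMS reference table
#'
#' Generates a clearly synthetic, fully valid LMS reference covering both
#' sexes over 24 to 240.5 months, so every part of the pipeline can be
#' exercised without distributing any survey-derived reference values. The
#' default shapes are chosen to look like a plausible pediatric BMI
#' reference: the median M dips to a nadir around the adiposity-rebound age
#' (5-6 y) and rises smoothly into the mid-20s kg/m^2 by age 20; the
#' coefficient of variation S grows with age within \[0.08, 0.16\]; the
#' Box-Cox power L is negative (right-skewed BMI) and drifts further
#' negative with age. Sexes differ slightly in level and rebound age.
#'
#' @param age_step Grid step in months (default 0.5, the usual reference
#'   granularity).
#' @param seed Unused by the default deterministic curves; kept so callers
#'   can treat the generator uniformly. The output is identical for any
#'   seed.
#' @return An [`lms_reference`][new_lms_reference].
#' @export
synth_reference <- function(age_step = 0.5, seed = 1L) {
  ages <- seq(24, 240.5, by = age_step)
  if (max(ages) < 240.5) ages <- c(ages, 240.5)
  build <- function(sex) {
    a <- ages / 12
    if (sex == "female") {
      M <- 15.5 + 0.050 * (a - 5.5)^2
      S <- 0.088 + 0.0034 * (a - 2)
      L <- -1.5 - 0.040 * (a - 2)
    } else {
      M <- 15.8 + 0.048 * (a - 5.8)^2
      S <- 0.085 + 0.0032 * (a - 2)
      L <- -1.3 - 0.050 * (a - 2)
    }
    data.frame(sex = sex, age_months = ages, L = L, M = M, S = S,
               stringsAsFactors = FALSE)
  }
  new_lms_reference(rbind(build("female"), build("male")))
}

# interior sampling margins that keep a generated subject safely inside its
# target category: 0.5 percentile points, 0.5 percent-of-P95, 0.1 kg/m^2
.margin_pct <- 0.5
.margin_p95 <- 0.5
.margin_bmi <- 0.1

# draw one BMI strictly interior to `status` at the given LMS parameters;
# returns list(bmi, arm) where arm records which criterion places it there
sample_interior_bmi <- function(status, L, M, S) {
  q <- function(p) bmi_at_percentile(p, L, M, S)
  p95 <- q(95)
  u <- stats::runif(1)
  pick <- function(lo, hi) lo + u * (hi - lo)
  # the absolute-BMI arm of class 2 overrides every percentile band, so a
  # percentile-interior draw must also stay below 35 kg/m^2; cap the band's
  # upper percentile at the percentile of (35 - margin) when it binds
  pct_band <- function(lo, hi) {
    cap_bmi <- 35 - .margin_bmi
    if (q(hi) >= cap_bmi) {
      hi <- min(hi, percentile_from_z(zscore_from_bmi(cap_bmi, L, M, S)) -
                  .margin_pct)
    }
    if (lo >= hi) return(list(bmi = NA_real_, arm = "infeasible"))
    list(bmi = q(pick(lo, hi)), arm = "percentile")
  }
  switch(status,
    "underweight" = pct_band(0.5, 5 - .margin_pct),
    "healthy weight" = pct_band(5 + .margin_pct, 85 - .margin_pct),
    "overweight" = pct_band(85 + .margin_pct, 95 - .margin_pct),
    "obese class 1" = {
      lo <- max(q(95 + .margin_pct), 1.002 * p95)
      hi <- min((1.2 - .margin_p95 / 100) * p95, 35 - .margin_bmi)
      if (lo >= hi) {  # reference makes class 1 vanishingly thin here
        list(bmi = NA_real_, arm = "infeasible")
      } else {
        list(bmi = pick(lo, hi), arm = "percentile")
      }
    },
    "severe obesity class 2" = {
      lo <- (1.2 + .margin_p95 / 100) * p95
      hi <- min((1.4 - .margin_p95 / 100) * p95, 40 - .margin_bmi)
      if (lo < hi) {
        list(bmi = pick(lo, hi), arm = "percent_of_p95")
      } else {
        # percent arm infeasible at this age: fall back to the absolute arm
        lo2 <- 35 + .margin_bmi
        hi2 <- min(40 - .margin_bmi, (1.4 - .margin_p95 / 100) * p95)
        if (lo2 >= hi2) return(list(bmi = NA_real_, arm = "infeasible"))
        list(bmi = pick(lo2, hi2), arm = "absolute_bmi")
      }
    },
    "severe obesity class 3" = {
      lo <- (1.4 + .margin_p95 / 100) * p95
      bmi <- pick(lo, lo * 1.15)
      list(bmi = bmi,
           arm = if (bmi >= 40 + .margin_bmi) "either" else "percent_of_p95")
    },
    stop("unknown status: ", status, call. = FALSE)
  )
}

# sex-specific median height (cm), linear in age; only used to back-solve
# plausible height/weight columns — BMI is the controlled quantity
synth_height_cm <- function(sex, age_y, noise_sd = 2.5) {
  base <- ifelse(sex == "female", 80 + 4.2 * age_y, 80 + 4.9 * age_y)
  pmax(base + stats::rnorm(length(age_y), 0, noise_sd), 65)
}

#' Synthetic cohort with known ground truth
#'
#' Draws subjects with ages uniform on \[2, 20) years, assigns each a target
#' weight-status category from `status_mix`, and inverts the LMS reference
#' to place the subject's BMI strictly interior to that category (margins:
#' 0.5 percentile points, 0.5 percent-of-P95, 0.1 kg/m^2), so the scoring
#' pipeline must recover the intended category exactly. Height is drawn from
#' a sex-specific linear-in-age model with mild noise and weight back-solved
#' from the BMI, so the height/weight columns reproduce the controlled BMI
#' exactly. In longitudinal mode each child receives 2-5 visits spanning at
#' most four years, keeping the child's category constant across visits.
#'
#' Where a category's percent-of-P95 band is infeasible at a drawn age
#' (possible for class 2 when 1.2x P95 already exceeds 40 kg/m^2), the
#' absolute-BMI arm is used instead and recorded in the ground truth `arm`
#' column; ages where no interior point exists are redrawn.
#'
#' @param n Number of subjects (children, in longitudinal mode).
#' @param reference An [`lms_reference`][load_lms_reference].
#' @param mode `"cross_sectional"` (unique IDs) or `"longitudinal"`
#'   (replicated IDs).
#' @param sex_ratio Proportion female (default 0.5).
#' @param status_mix Named proportions over [weight_status_levels]; must sum
#'   to 1. Default: uniform over the six categories.
#' @param seed Integer seed; identical seeds reproduce identical cohorts.
#' @return List with `cohort` (data.frame in the input schema: `ID`, `Sex`,
#'   `Age_y`, `Height_cm`, `Weight_kg`, `BMI` all `NA`) and `truth`
#'   (data.frame: `ID`, `Age_y`, `sex`, `bmi`, `target_status`, `arm`), one
#'   row per measurement in both.
#' @export
synth_cohort <- function(n, reference, mode = c("cross_sectional", "longitudinal"),
                         sex_ratio = 0.5,
                         status_mix = stats::setNames(rep(1 / 6, 6),
                                                      weight_status_levels),
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "lms_reference"), n >= 1,
            sex_ratio >= 0, sex_ratio <= 1)
  if (is.null(names(status_mix)) ||
      !all(names(status_mix) %in% weight_status_levels)) {
    stop("status_mix must be named with weight-status categories", call. = FALSE)
  }
  if (abs(sum(status_mix) - 1) > 1e-8) {
    stop("status_mix proportions must sum to 1", call. = FALSE)
  }
  set.seed(seed)
  sexes <- ifelse(stats::runif(n) < sex_ratio, "female", "male")
  targets <- sample(names(status_mix), n, replace = TRUE, prob = status_mix)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    visits <- if (mode == "longitudinal") sample(2:5, 1) else 1L
    repeat {
      if (mode == "longitudinal") {
        base <- stats::runif(1, 2, 16)
        gaps <- stats::runif(visits - 1, 0.3, 4 / max(visits - 1, 1))
        ages <- base + c(0, cumsum(gaps))
      } else {
        ages <- stats::runif(1, 2, 20 - 1e-6)
      }
      ages <- round(ages, 3)  # drawn at file precision so scoring sees the same age
      draw <- lapply(ages, function(a) {
        lms <- interpolate_lms(reference, sexes[i], a * 12)
        sample_interior_bmi(targets[i], lms$L, lms$M, lms$S)
      })
      bmis <- vapply(draw, `[[`, 0, "bmi")
      if (!anyNA(bmis)) break
    }
    h <- synth_height_cm(sexes[i], ages)
    rows[[i]] <- data.frame(
      ID = sprintf("S%04d", i),
      Sex = ifelse(sexes[i] == "female", "F", "M"),
      Age_y = ages,
      Height_cm = round(h, 1),
      bmi = bmis,
      target_status = targets[i],
      arm = vapply(draw, `[[`, "", "arm"),
      stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, rows)
  # weight back-solved from the rounded height so BMI is reproduced exactly
  all$Weight_kg <- all$bmi * (all$Height_cm / 100)^2
  cohort <- data.frame(ID = all$ID, Sex = all$Sex, Age_y = all$Age_y,
                       Height_cm = all$Height_cm,
                       Weight_kg = all$Weight_kg,
                       BMI = NA_real_, stringsAsFactors = FALSE)
  truth <- data.frame(ID = all$ID, Age_y = all$Age_y,
                      sex = ifelse(all$Sex == "F", "female", "male"),
                      bmi = all$bmi, target_status = all$target_status,
                      arm = all$arm, stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Write a synthetic cohort and its ground truth to disk
#'
#' @param synth Result of [synth_cohort()].
#' @param dir Output directory.
#' @param stem File stem; writes `<stem>.csv` (input schema) and
#'   `<stem>_truth.csv` (side-car ground truth).
#' @return Character vector of the two paths, invisibly.
#' @export
write_synth_cohort <- function(synth, dir = ".", stem = "synthetic_cohort") {
  cohort_path <- file.path(dir, paste0(stem, ".csv"))
  truth_path <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(synth$cohort, cohort_path, row.names = FALSE, na = "")
  utils::write.csv(synth$truth, truth_path, row.names = FALSE, na = "")
  invisible(c(cohort = cohort_path, truth = truth_path))
}
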