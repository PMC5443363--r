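#' Body mass index from height and weight
#'
#' BMI (kg/m^2) is weight in kilograms divided by height in metres squared.
#'
#' @param height_cm Height in centimetres. Must be positive.
#' @param weight_kg Weight in kilograms. Must be positive.
#' @return BMI in kg/m^2, unrounded. Vectorised with recycling.
#' @examples
#' bmi_from_hw(100, 16)  # 16
#' bmi_from_hw(163.5, 52.3)
#' @export
bmi_from_hw <- function(height_cm, weight_kg) {
  stopifnot(is.numeric(height_cm), is.numeric(weight_kg))
  if (any(!is.finite(height_cm) | height_cm <= 0)) {
    stop("height_cm must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(weight_kg) | weight_kg <= 0)) {
    stop("weight_kg must be positive and finite", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

#' LMS z-score for a measurement
#'
#' Standard Cole LMS transform: for Box-Cox power L, median M and coefficient
#' of variation S,
#' \deqn{z = \frac{(x/M)^L - 1}{L S} \quad (L \neq 0), \qquad
#'       z = \frac{\log(x/M)}{S} \quad (L = 0).}
#' The L = 0 log branch is the analytic limit of the power branch.
#'
#' @param bmi Measurement (here BMI, kg/m^2); positive.
#' @param L Box-Cox power (dimensionless).
#' @param M Median of the reference distribution (same units as `bmi`); positive.
#' @param S Coefficient of variation; positive.
#' @return z-score on the standard normal scale. No truncation is applied:
#'   extreme values in the severe-obesity tail are reported as-is.
#' @export
zscore_from_bmi <- function(bmi, L, M, S) {
  stopifnot(is.numeric(bmi), is.numeric(L), is.numeric(M), is.numeric(S))
  if (any(!is.finite(bmi) | bmi <= 0)) stop("bmi must be positive", call. = FALSE)
  if (any(!is.finite(M) | M <= 0)) stop("M must be positive", call. = FALSE)
  if (any(!is.finite(S) | S <= 0)) stop("S must be positive", call. = FALSE)
  n <- max(length(bmi), length(L), length(M), length(S))
  bmi <- rep_len(bmi, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- log(bmi / M) / S
  pow <- L != 0
  z[pow] <- ((bmi[pow] / M[pow])^L[pow] - 1) / (L[pow] * S[pow])
  z
}

#' Percentile from a z-score
#'
#' @param z Finite z-score(s).
#' @return `pnorm(z) * 100`, a percentile in the open interval (0, 100)
#'   up to floating-point underflow at extreme `|z|`.
#' @export
percentile_from_z <- function(z) {
  stopifnot(is.numeric(z))
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  stats::pnorm(z) * 100
}

#' BMI at a given percentile of an LMS distribution
#'
#' Inverse of [zscore_from_bmi()]: with \eqn{z = \Phi^{-1}(p/100)},
#' returns \eqn{M (1 + L S z)^{1/L}} for L != 0 and \eqn{M e^{S z}} for L = 0.
#'
#' @inheritParams zscore_from_bmi
#' @param p Percentile in (0, 100).
#' @return BMI (kg/m^2) at that percentile. Errors when `1 + L*S*z <= 0`,
#'   where the Box-Cox distribution is undefined.
#' @export
bmi_at_percentile <- function(p, L, M, S) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p) | p <= 0 | p >= 100)) {
    stop("p must lie strictly between 0 and 100", call. = FALSE)
  }
  if (any(!is.finite(M) | M <= 0)) stop("M must be positive", call. = FALSE)
  if (any(!is.finite(S) | S <= 0)) stop("S must be positive", call. = FALSE)
  n <- max(length(p), length(L), length(M), length(S))
  p <- rep_len(p, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- stats::qnorm(p / 100)
  out <- M * exp(S * z)
  pow <- L != 0
  base <- 1 + L[pow] * S[pow] * z[pow]
  if (any(base <= 0)) {
    stop("distribution undefined at this extreme: 1 + L*S*z <= 0", call. = FALSE)
  }
  out[pow] <- M[pow] * base^(1 / L[pow])
  out
}

#' BMI as a percent of the 95th percentile
#'
#' The key metric for grading severe obesity: 120% and 140% of the
#' sex/age-specific 95th percentile are the class 2 and class 3 cut points.
#'
#' @param bmi Subject BMI (kg/m^2), positive.
#' @param p95_bmi BMI at the 95th percentile for the subject's sex and age,
#'   positive.
#' @return `100 * bmi / p95_bmi`.
#' @export
pct_of_p95 <- function(bmi, p95_bmi) {
  stopifnot(is.numeric(bmi), is.numeric(p95_bmi))
  if (any(!is.finite(bmi) | bmi <= 0)) stop("bmi must be positive", call. = FALSE)
  if (any(!is.finite(p95_bmi) | p95_bmi <= 0)) {
    stop("p95_bmi must be positive", call. = FALSE)
  }
  100 * bmi / p95_bmi
}
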