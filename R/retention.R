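#' @keywords internal
"_PACKAGE"

## minutes in a day; denominator constant of the Reberg clearance formula
MINUTES_PER_DAY <- 1440

#' Body-surface correction factor
#'
#' Mosteller-style body-surface factor used to normalise renal filtration to
#' the population-average 1.73 m2 body surface.  Two readings of the
#' correction are provided: \code{"printed"} multiplies the Mosteller radical
#' by 1.73, i.e. \eqn{1.73\sqrt{WH/3600}}; \code{"mosteller_ratio"} divides
#' the Mosteller BSA by 1.73 m2, the conventional clinical normalisation,
#' i.e. \eqn{\sqrt{WH/3600}/1.73}.  The default is \code{"printed"}.
#'
#' @param weight_kg body weight in kg (positive).
#' @param height_cm standing height in cm (positive).
#' @param variant \code{"printed"} (default) or \code{"mosteller_ratio"}.
#' @return dimensionless positive correction factor (vectorised).
#' @examples
#' body_surface(36, 100)                      # radical is 1 -> 1.73
#' body_surface(36, 100, "mosteller_ratio")   # -> 1/1.73
#' @export
body_surface <- function(weight_kg, height_cm,
                         variant = c("printed", "mosteller_ratio")) {
  variant <- match.arg(variant)
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("'weight_kg' must be positive and finite", call. = FALSE)
  if (any(!is.finite(height_cm)) || any(height_cm <= 0))
    stop("'height_cm' must be positive and finite", call. = FALSE)
  radical <- sqrt(weight_kg * height_cm / 3600)
  switch(variant,
         printed         = 1.73 * radical,
         mosteller_ratio = radical / 1.73)
}

#' Renal metal clearance (Reberg formula)
#'
#' Clearance of a metal from blood plasma, in mL/min, estimated from the
#' urine/blood concentration ratio, the daily urine volume and the
#' body-surface correction:
#' \deqn{CL = \frac{c^{urine} D}{c^{blood} \cdot 1440 \cdot BS}}
#' where 1440 is the number of minutes in a day.
#'
#' @param urine_conc metal concentration in urine, ug/mL (non-negative).
#' @param blood_conc metal concentration in blood, ug/mL (strictly positive).
#' @param diuresis daily urine volume, mL (positive).
#' @param bs body-surface correction from [body_surface()] (positive).
#' @return clearance in mL/min (vectorised); zero iff \code{urine_conc} is zero.
#' @examples
#' clearance_reberg(1, 1, 1440, 1)   # the 1440 cancels -> 1 mL/min
#' @export
clearance_reberg <- function(urine_conc, blood_conc, diuresis, bs) {
  if (any(!is.finite(urine_conc)) || any(urine_conc < 0))
    stop("'urine_conc' must be non-negative and finite", call. = FALSE)
  if (any(!is.finite(blood_conc)) || any(blood_conc <= 0))
    stop("'blood_conc' must be strictly positive: clearance is unmeasurable ",
         "when the blood concentration is zero", call. = FALSE)
  if (any(!is.finite(diuresis)) || any(diuresis <= 0))
    stop("'diuresis' must be positive and finite", call. = FALSE)
  if (any(!is.finite(bs)) || any(bs <= 0))
    stop("'bs' must be strictly positive", call. = FALSE)
  (urine_conc * diuresis) / (blood_conc * MINUTES_PER_DAY * bs)
}

#' Retention from clearance
#'
#' The dimensionless retention statistic, a Gaussian kernel of the clearance
#' measured in units of the cohort clearance spread:
#' \deqn{Retention = \exp(-CL^2 / (2\sigma^2)) \in (0;1]}
#' Zero clearance (no excretion) gives maximal retention 1; retention is
#' strictly decreasing in clearance.
#'
#' @param clearance clearance in mL/min (non-negative, vectorised).
#' @param sigma standard deviation of the cohort clearance series, mL/min
#'   (strictly positive scalar).
#' @return retention values in (0;1].
#' @examples
#' retention_from_clearance(0, 2)      # 1
#' retention_from_clearance(2, 2)      # exp(-0.5)
#' @export
retention_from_clearance <- function(clearance, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a single positive number (degenerate cohort ",
         "spread otherwise)", call. = FALSE)
  if (any(!is.finite(clearance)) || any(clearance < 0))
    stop("'clearance' must be non-negative and finite", call. = FALSE)
  exp(-clearance^2 / (2 * sigma^2))
}

#' Retention series for a cohort clearance vector
#'
#' Computes the spread sigma of a clearance series and maps every element
#' through [retention_from_clearance()].  sigma may be the population
#' (n denominator, default) or sample (n-1) standard deviation.
#'
#' @param clearances numeric vector of clearances, mL/min; at least two
#'   values with non-zero spread.
#' @param sigma_mode \code{"population"} (default) or \code{"sample"}.
#' @return a list of class \code{"retention_series"} with elements
#'   \code{retention} (same order as input), \code{clearance}, \code{sigma}
#'   and \code{sigma_mode}.
#' @export
retention_series <- function(clearances,
                             sigma_mode = c("population", "sample")) {
  sigma_mode <- match.arg(sigma_mode)
  if (length(clearances) < 2L)
    stop("need at least 2 clearance values to estimate the spread",
         call. = FALSE)
  sigma <- series_sd(clearances, sigma_mode)
  if (!is.finite(sigma) || sigma <= 0)
    stop("clearance series has zero spread: sigma is degenerate",
         call. = FALSE)
  structure(
    list(retention  = retention_from_clearance(clearances, sigma),
         clearance  = clearances,
         sigma      = sigma,
         sigma_mode = sigma_mode),
    class = "retention_series")
}

series_sd <- function(x, mode) {
  n <- length(x)
  if (mode == "population") sqrt(sum((x - mean(x))^2) / n) else stats::sd(x)
}

#' @export
print.retention_series <- function(x, ...) {
  cat("Retention series: n =", length(x$retention),
      sprintf("| sigma = %.6g mL/min (%s)\n", x$sigma, x$sigma_mode))
  cat("  retention range:",
      sprintf("[%.4f, %.4f]\n", min(x$retention), max(x$retention)))
  invisible(x)
}
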