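#' Two-fold serial blood dilution series
#'
#' Successive halving from a starting blood volume fraction, plus the 0
#' blank: the erythema-standard layout of a 6-well plate (50%, 25%, 12.5%,
#' 6.25%, 3.125%, 0%).
#'
#' @param start Starting fraction in (0, 1\]. Default 0.5.
#' @param steps Number of non-blank wells (>= 1). Default 5.
#' @return Numeric vector `c(start, start/2, ..., start/2^(steps-1), 0)`.
#' @examples
#' dilution_series() # 0.50 0.25 0.125 0.0625 0.03125 0
#' @export
dilution_series <- function(start = 0.5, steps = 5L) {
  if (!is.numeric(start) || length(start) != 1L || start <= 0 || start > 1) {
    stop("`start` must be a fraction in (0, 1]", call. = FALSE)
  }
  if (steps < 1L) stop("`steps` must be >= 1", call. = FALSE)
  c(start / 2^(0:(steps - 1L)), 0)
}

#' Fit the erythema standard curve
#'
#' Ordinary least-squares line through (concentration, response) points of a
#' blood-dilution standard, with its coefficient of determination. The
#' response may be any scalar color statistic (mean red of a well region,
#' spectrophotometric optical density, ...).
#'
#' @param data Data frame holding the standard.
#' @param concentration,response Columns of `data` (tidy-eval); default to
#'   columns named `concentration` and `response`.
#' @return A `calibration_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `n_points`, and the fitted `model` ([stats::lm] object).
#'   When all responses are equal, the curve has slope 0 and `r_squared`
#'   is defined as 0.
#' @examples
#' std <- data.frame(concentration = dilution_series(),
#'                   response = 0.4432 * dilution_series() - 0.0282)
#' fit_standard(std)
#' @export
fit_standard <- function(data, concentration = concentration,
                         response = response) {
  conc <- dplyr::pull(data, {{ concentration }})
  resp <- dplyr::pull(data, {{ response }})
  if (length(conc) != length(resp) || length(conc) < 3L) {
    stop("need at least 3 paired (concentration, response) points",
         call. = FALSE)
  }
  if (length(unique(conc)) < 2L) {
    stop("degenerate fit: all concentrations identical", call. = FALSE)
  }
  fit <- stats::lm(resp ~ conc)
  ss_tot <- sum((resp - mean(resp))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         n_points = length(conc),
         model = fit),
    class = "calibration_curve"
  )
}

#' Construct a calibration curve from known coefficients
#'
#' Builds a `calibration_curve` directly from a published slope and
#' intercept, e.g. to apply a previously fitted erythema standard to new
#' photographs.
#'
#' @param slope,intercept Line coefficients (response units per unit
#'   concentration; response units).
#' @param r_squared Optional coefficient of determination in \[0, 1\].
#' @param n_points Number of points behind the fit (>= 3), if known.
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, r_squared = NA_real_,
                              n_points = NA_integer_) {
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         n_points = n_points, model = NULL),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> response = %.4f * concentration %+.4f",
              x$slope, x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.4f, n = %s)",
                                       x$r_squared, x$n_points))
  cat("\n")
  invisible(x)
}

#' @describeIn fit_standard Coefficients as a two-row tibble.
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @describeIn fit_standard One-row fit summary.
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_points = x$n_points)
}

#' Invert a calibration curve to a blood-concentration equivalent
#'
#' Maps a measured response back through the standard line,
#' `x = (response - intercept) / slope`, and clamps into the reporting
#' range: whole-photograph responses routinely fall outside the standard,
#' and severities are expressed as 0-80% blood-concentration equivalents.
#'
#' @param curve A `calibration_curve` with nonzero slope.
#' @param response Numeric vector of measured responses.
#' @param range Clamping interval; default `c(0, 0.8)`.
#' @return Numeric vector of concentrations in `range`.
#' @export
predict_concentration <- function(curve, response, range = c(0, 0.8)) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) {
    stop("cannot invert a flat calibration curve (slope 0)", call. = FALSE)
  }
  pmin(pmax((response - curve$intercept) / curve$slope, range[1]), range[2])
}

#' Bin a blood-concentration equivalent into severity bands
#'
#' Tiles \[0, 0.8\] into eight 10%-wide bins and flags the severe range:
#' concentrations at or above 0.60, the balance point of the severe,
#' swollen erythema.
#'
#' @param concentration Numeric vector of clamped concentrations in
#'   \[0, 0.8\].
#' @param severe_cutoff Severe-flag boundary; default 0.60.
#' @return A tibble with one row per input: `concentration`, `bin_lower`,
#'   `bin_upper` (half-open bins except the top bin, which closes at 0.8),
#'   and `severe`.
#' @export
bin_severity <- function(concentration, severe_cutoff = 0.6) {
  if (any(concentration < 0 | concentration > 0.8)) {
    stop("concentrations must be clamped to [0, 0.8] first", call. = FALSE)
  }
  # guard against 0.6 / 0.1 landing just below 6 in floating point
  idx <- pmin(floor(concentration / 0.1 + 1e-9), 7)
  tibble::tibble(
    concentration = concentration,
    bin_lower = idx * 0.1,
    bin_upper = (idx + 1) * 0.1,
    severe = concentration >= severe_cutoff
  )
}

#' Read a standard-curve CSV
#'
#' One standard per file, columns `concentration` and `response` (any
#' additional response columns are kept so a spectrophotometric series can
#' ride alongside an image-derived one).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_standard_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  if (!all(c("concentration", "response") %in% names(out))) {
    stop("standard CSV needs `concentration` and `response` columns",
         call. = FALSE)
  }
  out
}
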