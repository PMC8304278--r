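# HRMS-tier quantification: calibration fitting, LOD/LOQ from the
# low-concentration curve, censored back-calculation to the sample scale,
# and recovery / precision statistics.

#' Fit a calibration curve
#'
#' Ordinary least-squares line of response on concentration. The intercept's
#' standard error is the SD used by the LOD/LOQ formulas.
#'
#' @param data Data frame with columns `conc` (µg/mL) and `response`.
#' @param species Optional species label carried on the fit.
#' @return A `calibration_fit` object (see [tidy.calibration_fit()] and
#'   [glance.calibration_fit()]).
#' @export
#' @examples
#' fit_calibration(tibble::tibble(conc = c(1, 2, 4, 8), response = c(3.1, 6.2, 12.1, 24.2)))
fit_calibration <- function(data, species = NA_character_) {
  stopifnot(all(c("conc", "response") %in% names(data)))
  conc <- data$conc
  resp <- data$response
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct calibration levels", call. = FALSE)
  }
  fit <- stats::lm(resp ~ conc)
  # summary.lm warns on exact lines ("essentially perfect fit"); a zero
  # intercept SD is a legitimate calibration outcome here
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive; degenerate series", call. = FALSE)
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((resp - mean(resp))^2)
  structure(
    list(
      fit = fit,
      species = species,
      levels = conc,
      responses = resp,
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      sd_intercept = unname(sm$coefficients[1, 2]),
      r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit%s: slope %.4g, intercept %.4g (SD %.3g), R2 %.6f, %d levels>\n",
              if (!is.na(x$species)) paste0(" ", x$species) else "",
              x$slope, x$intercept, x$sd_intercept, x$r_squared,
              length(x$levels)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.calibration_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(co[, 1]),
    std.error = unname(co[, 2])
  )
}

#' One-row summary of a calibration fit
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return Tibble: `species`, `slope`, `intercept`, `sd_intercept`,
#'   `r_squared`, `lod`, `loq`, `n_levels`.
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    species = x$species, slope = x$slope, intercept = x$intercept,
    sd_intercept = x$sd_intercept, r_squared = x$r_squared,
    lod = lod(x), loq = loq(x), n_levels = length(x$levels)
  )
}

#' Limit of detection / quantification of a calibration curve
#'
#' `LOD = 3.3 * SD / b` and `LOQ = 10 * SD / b`, with SD the standard
#' deviation of the intercept and b the slope of the low-concentration
#' calibration curve. Their ratio is 10/3.3 for every valid curve.
#'
#' @param curve A `calibration_fit`.
#' @return Concentration on the calibration scale (µg/mL).
#' @export
lod <- function(curve) {
  stopifnot(inherits(curve, "calibration_fit"))
  if (curve$slope <= 0) stop("slope must be > 0", call. = FALSE)
  3.3 * curve$sd_intercept / curve$slope
}

#' @rdname lod
#' @export
loq <- function(curve) {
  stopifnot(inherits(curve, "calibration_fit"))
  if (curve$slope <= 0) stop("slope must be > 0", call. = FALSE)
  10 * curve$sd_intercept / curve$slope
}

#' Restrict a calibration series to its low-concentration levels
#'
#' The LOD/LOQ formulas use the low-concentration curve; by default the
#' lowest three levels of the series.
#'
#' @param data Calibration data frame (`conc`, `response`).
#' @param n_levels Number of lowest distinct levels to keep.
#' @return The filtered data frame.
#' @export
low_concentration <- function(data, n_levels = 3L) {
  keep <- sort(unique(data$conc))[seq_len(min(n_levels, length(unique(data$conc))))]
  data[data$conc %in% keep, , drop = FALSE]
}

#' Back-calculate a sample amount from a detection record
#'
#' Converts an instrument response to µg/g of sample through the extraction
#' scheme (default: 2 g homogenate brought to 40 mL, extract diluted 1:10
#' before injection), then censors against the curve's LOD/LOQ on the same
#' sample scale: below LOD reports `"<LOD"`, between LOD and LOQ `"<LOQ"`,
#' and an unconfirmed record with no signal `"ND"`.
#'
#' Long-chain species have no reference standards and cannot be quantified;
#' asking for a curve-less quantification is an error (they are
#' fingerprint-only).
#'
#' @param record One-row detection record (from [confirm_species()]), with a
#'   `response` column added (peak area of the precursor XIC), or a plain
#'   list with `species`, `confirmed`, `response`.
#' @param curve `calibration_fit` for the species, or `NULL`.
#' @param sample_mass Sample intake, g.
#' @param extract_volume Extract volume, mL.
#' @param dilution Dilution factor before injection.
#' @return The record with `amount` (µg/g, `NA` when censored) and
#'   `censoring` (`"ND"`, `"<LOD"`, `"<LOQ"` or `"quantified"`) filled in.
#' @export
quantify_species <- function(record, curve, sample_mass = 2,
                             extract_volume = 40, dilution = 10) {
  if (is.null(curve)) {
    stop("no standard for species '", record$species,
         "'; fingerprint only, not individually quantifiable", call. = FALSE)
  }
  stopifnot(inherits(curve, "calibration_fit"))
  factor_sample <- dilution * extract_volume / sample_mass
  resp <- record$response
  if (is.null(resp) || is.na(resp) || resp <= 0) {
    record$amount <- NA_real_
    record$censoring <- "ND"
    return(record)
  }
  conc <- (resp - curve$intercept) / curve$slope  # µg/mL injected
  amount <- conc * factor_sample                  # µg/g sample
  lod_s <- lod(curve) * factor_sample
  loq_s <- loq(curve) * factor_sample
  if (amount < lod_s) {
    record$amount <- NA_real_
    record$censoring <- "<LOD"
  } else if (amount < loq_s) {
    record$amount <- NA_real_
    record$censoring <- "<LOQ"
  } else {
    record$amount <- amount
    record$censoring <- "quantified"
  }
  record
}

#' Extraction recovery
#'
#' Percent ratio of the response of a blank spiked before extraction to the
#' same blank spiked after extraction.
#'
#' @param spiked_before,spiked_after Responses.
#' @return Recovery in percent.
#' @export
#' @examples
#' recovery(83, 100)
recovery <- function(spiked_before, spiked_after) {
  if (any(spiked_after == 0)) {
    stop("spiked-after response is zero; recovery undefined", call. = FALSE)
  }
  100 * spiked_before / spiked_after
}

#' Intra- and inter-day precision (CV%)
#'
#' Within-day coefficient of variation (100 * sd / mean per day, averaged
#' across days) and the between-day CV of the day means.
#'
#' @param data Data frame with columns `day` and `response`.
#' @return One-row tibble: `intra_day_cv`, `inter_day_cv`.
#' @export
#' @examples
#' precision(tibble::tibble(day = rep(1:3, each = 3),
#'                          response = c(90, 100, 110, 95, 100, 105, 99, 100, 101)))
precision <- function(data) {
  stopifnot(all(c("day", "response") %in% names(data)))
  counts <- table(data$day)
  if (any(counts < 2L)) {
    stop("need at least 2 replicates per day", call. = FALSE)
  }
  if (any(tapply(data$response, data$day, mean) == 0)) {
    stop("zero mean response; CV undefined", call. = FALSE)
  }
  per_day <- tapply(data$response, data$day, function(x) 100 * stats::sd(x) / mean(x))
  day_means <- tapply(data$response, data$day, mean)
  inter <- if (length(day_means) >= 2L) {
    100 * stats::sd(day_means) / mean(day_means)
  } else {
    NA_real_
  }
  tibble::tibble(intra_day_cv = mean(per_day), inter_day_cv = inter)
}
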