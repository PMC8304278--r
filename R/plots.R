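# ggplot2 graphics for traces, detected peaks and calibration fits.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   geom_abline labs theme_minimal annotate
#' @export
ggplot2::autoplot

#' Plot a chromatographic trace
#'
#' @param object A `phos_trace`.
#' @param peaks Optional peak tibble from [detect_peaks()]; apexes are
#'   marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phos_trace <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = time, y = intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "retention time (min)",
      y = if (attr(object, "channel") == "SCD") "conductivity (a.u.)"
          else "intensity (a.u.)",
      title = if (!is.na(attr(object, "target_mz")))
        sprintf("XIC m/z %.4f", attr(object, "target_mz"))
      else attr(object, "sample_id")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = apex_time, y = height),
      colour = "red", shape = 17
    )
  }
  p
}

#' Plot a calibration fit
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot showing the points, the fitted line and R^2.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  d <- tibble::tibble(conc = object$levels, response = object$responses)
  ggplot2::ggplot(d, ggplot2::aes(x = conc, y = response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(
      x = "concentration (ug/mL)", y = "response",
      title = sprintf("%s calibration (R2 = %.5f)",
                      ifelse(is.na(object$species), "", object$species),
                      object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot verdict counts for a set of samples
#'
#' @param verdicts Verdict tibble from [classify_sample()].
#' @return A ggplot bar chart of verdict labels.
#' @export
plot_verdicts <- function(verdicts) {
  ggplot2::ggplot(verdicts, ggplot2::aes(x = label)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "samples") +
    ggplot2::theme_minimal()
}
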