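# Chromatographic trace container and delimited I/O.
#
# A trace is a tibble with `time` (minutes, strictly increasing) and
# `intensity` columns, plus attributes identifying the channel (SCD
# conductometric signal or an extracted-ion chromatogram) and, for XICs,
# the target m/z.

#' Construct a chromatographic trace
#'
#' @param time Numeric vector of retention times in minutes, strictly
#'   increasing.
#' @param intensity Numeric vector of the same length; finite.
#' @param channel `"SCD"` (conductometric) or `"XIC"` (extracted ion).
#' @param sample_id Optional sample label.
#' @param target_mz Target m/z (Th); XIC traces only.
#' @return A `phos_trace` tibble.
#' @export
#' @examples
#' new_trace(seq(0, 1, 0.1), rexp(11), channel = "SCD")
new_trace <- function(time, intensity, channel = c("SCD", "XIC"),
                      sample_id = NA_character_, target_mz = NA_real_) {
  channel <- match.arg(channel)
  if (length(time) < 2L) stop("a trace needs at least 2 points", call. = FALSE)
  if (length(time) != length(intensity)) {
    stop("time and intensity must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop("trace times must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("trace intensities must be finite", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(time),
                        intensity = as.numeric(intensity))
  attr(out, "channel") <- channel
  attr(out, "sample_id") <- sample_id
  attr(out, "target_mz") <- target_mz
  class(out) <- c("phos_trace", class(out))
  out
}

#' @export
print.phos_trace <- function(x, ...) {
  cat(sprintf("<phos_trace: %s channel, %d points, %.2f-%.2f min%s>\n",
              attr(x, "channel"), nrow(x), min(x$time), max(x$time),
              if (!is.na(attr(x, "target_mz")))
                sprintf(", m/z %.4f", attr(x, "target_mz")) else ""))
  NextMethod()
}

trace_dt <- function(trace) stats::median(diff(trace$time))

#' Read a two-column delimited trace file
#'
#' Accepts comma- or semicolon-separated text with either `.` or `,` decimal
#' marks, header optional. Time in minutes by default; `time_unit = "sec"`
#' converts on read.
#'
#' @param path File path.
#' @param sep Field separator.
#' @param dec Decimal mark.
#' @param time_unit `"min"` or `"sec"`.
#' @inheritParams new_trace
#' @return A `phos_trace`.
#' @export
read_trace <- function(path, sep = ",", dec = ".", time_unit = c("min", "sec"),
                       channel = "SCD", sample_id = NA_character_) {
  time_unit <- match.arg(time_unit)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  d <- utils::read.table(path, sep = sep, dec = dec, header = has_header,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("trace file must have two columns", call. = FALSE)
  t <- as.numeric(d[[1]])
  if (time_unit == "sec") t <- t / 60
  if (any(diff(t) <= 0)) {
    stop("non-monotone time column in ", path, call. = FALSE)
  }
  new_trace(t, as.numeric(d[[2]]), channel = channel, sample_id = sample_id)
}

#' @rdname read_trace
#' @param trace A `phos_trace`.
#' @export
write_trace <- function(trace, path, sep = ",", dec = ".") {
  d <- data.frame(time = trace$time, intensity = trace$intensity)
  utils::write.table(d, path, sep = sep, dec = dec, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
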