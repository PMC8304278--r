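# Conductometric-channel screening: relative retention times against the
# orthophosphate anchor, the qualitative 200 µg/g screening decision, and
# the screening-validation statistics (specificity, false-positive rule,
# linearity).
#
# Screening is qualitative by design: the 200 µg/g cut-off lives in the
# spiked reference run the RRT table is built from, and the screen reports
# detect / non-detect only. Quantification belongs to the HRMS tier.

#' Relative retention time
#'
#' Ratio of a peak's retention time to the orthophosphate reference peak's.
#'
#' @param peak_rt Peak retention time, minutes.
#' @param ortho_rt Orthophosphate retention time, minutes (> 0).
#' @return The ratio.
#' @export
#' @examples
#' relative_rt(9.0, 5.9)
relative_rt <- function(peak_rt, ortho_rt) {
  if (!is.numeric(ortho_rt) || length(ortho_rt) != 1L || is.na(ortho_rt) ||
      ortho_rt <= 0) {
    stop("orthophosphate reference peak not found (ortho_rt must be > 0)",
         call. = FALSE)
  }
  peak_rt / ortho_rt
}

#' Match a relative retention time against a reference
#'
#' Accepts when the relative deviation is at most `tol` (default 2.5%).
#'
#' @param sample_rrt,reference_rrt Relative retention times (> 0).
#' @param tol Maximum relative deviation.
#' @return Logical.
#' @export
#' @examples
#' match_rrt(1.55, 1.5254)   # 1.6% off -> TRUE
#' match_rrt(1.60, 1.5254)   # 4.9% off -> FALSE
match_rrt <- function(sample_rrt, reference_rrt, tol = 0.025) {
  stopifnot(all(sample_rrt > 0), all(reference_rrt > 0))
  # small epsilon so a deviation of exactly tol is accepted despite
  # floating-point representation
  abs(sample_rrt - reference_rrt) / reference_rrt <= tol + 1e-12
}

#' Build a relative-retention-time reference from a spiked run
#'
#' Detects peaks in a run spiked at the screening cut-off, anchors on the
#' first detected peak (orthophosphate, the earliest-eluting anion and the
#' matrix's dominant natural peak), assigns the short-chain additive species
#' by proximity to their nominal retention times, and records the envelope
#' peaks in the SHMP window as the envelope RRT list.
#'
#' @param trace Spiked-run SCD `phos_trace`.
#' @param min_snr Minimum S/N for reference peaks.
#' @param nominal_rts Named vector of nominal retention times used to label
#'   the species peaks; defaults to the database values.
#' @param shmp_window Time window (min) holding the SHMP envelope.
#' @param column Label of the anion-exchange column the run used (reference
#'   tables are column-specific).
#' @return An `rrt_reference` list: `ortho_rt`, `species` (tibble
#'   name/rrt), `shmp_rrt` (numeric, up to 10), `column`.
#' @export
build_rrt_reference <- function(trace, min_snr = 3,
                                nominal_rts = NULL,
                                shmp_window = c(14, 28),
                                column = "AS16") {
  if (is.null(nominal_rts)) {
    db <- phosphate_species()
    want <- c("pyrophosphate", "triphosphate", "trimetaphosphate")
    nominal_rts <- stats::setNames(
      db$expected_rt[match(c("orthophosphate", want), db$name)],
      c("orthophosphate", want)
    )
  }
  pks <- detect_peaks(trace, min_snr = min_snr)
  if (nrow(pks) == 0L) {
    stop("orthophosphate reference peak not found in spiked run",
         call. = FALSE)
  }
  ortho_rt <- pks$apex_time[1]
  species <- names(nominal_rts)[names(nominal_rts) != "orthophosphate"]
  rrt <- vapply(species, function(s) {
    d <- abs(pks$apex_time - nominal_rts[[s]])
    if (min(d) > 0.5) return(NA_real_)
    relative_rt(pks$apex_time[which.min(d)], ortho_rt)
  }, numeric(1))
  env <- pks[pks$apex_time >= shmp_window[1] &
               pks$apex_time <= shmp_window[2], ]
  env <- utils::head(dplyr::arrange(env, apex_time), 10L)
  structure(
    list(
      ortho_rt = ortho_rt,
      species = tibble::tibble(name = species, rrt = unname(rrt)),
      shmp_rrt = relative_rt(env$apex_time, ortho_rt),
      column = column
    ),
    class = "rrt_reference"
  )
}

#' Persist / load an RRT reference table
#' @param ref An `rrt_reference`.
#' @param path CSV path.
#' @return `read_rrt_reference()` returns an `rrt_reference`.
#' @export
write_rrt_reference <- function(ref, path) {
  d <- rbind(
    data.frame(name = "orthophosphate", rrt = 1, kind = "anchor",
               stringsAsFactors = FALSE),
    data.frame(name = ref$species$name, rrt = ref$species$rrt,
               kind = "species", stringsAsFactors = FALSE),
    if (length(ref$shmp_rrt))
      data.frame(name = paste0("shmp_", seq_along(ref$shmp_rrt)),
                 rrt = ref$shmp_rrt, kind = "shmp",
                 stringsAsFactors = FALSE)
  )
  attr_line <- sprintf("# ortho_rt=%.6f column=%s", ref$ortho_rt, ref$column)
  writeLines(c(attr_line, "name,rrt,kind"), path)
  utils::write.table(d, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_rrt_reference
#' @export
read_rrt_reference <- function(path) {
  hdr <- readLines(path, n = 1L)
  ortho_rt <- as.numeric(sub(".*ortho_rt=([0-9.]+).*", "\\1", hdr))
  column <- sub(".*column=(\\S+).*", "\\1", hdr)
  d <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  structure(
    list(
      ortho_rt = ortho_rt,
      species = tibble::tibble(name = d$name[d$kind == "species"],
                               rrt = d$rrt[d$kind == "species"]),
      shmp_rrt = d$rrt[d$kind == "shmp"],
      column = column
    ),
    class = "rrt_reference"
  )
}

screen_one <- function(trace, reference, min_snr, rrt_tol, min_shmp_run) {
  pks <- detect_peaks(trace, min_snr = min_snr)
  if (nrow(pks) == 0L) {
    stop("orthophosphate reference peak not found in sample trace",
         call. = FALSE)
  }
  ortho_rt <- pks$apex_time[1]
  rrts <- relative_rt(pks$apex_time, ortho_rt)
  matches <- tibble::tibble(
    name = reference$species$name,
    reference_rrt = reference$species$rrt,
    matched = FALSE, sample_rrt = NA_real_, snr = NA_real_
  )
  for (i in seq_len(nrow(matches))) {
    if (is.na(matches$reference_rrt[i])) next
    ok <- match_rrt(rrts, matches$reference_rrt[i], rrt_tol) &
      pks$snr >= min_snr & rrts > 1 + rrt_tol  # exclude the anchor itself
    if (any(ok)) {
      j <- which(ok)[which.max(pks$height[ok])]
      matches$matched[i] <- TRUE
      matches$sample_rrt[i] <- rrts[j]
      matches$snr[i] <- pks$snr[j]
    }
  }
  shmp_hit <- rep(FALSE, length(reference$shmp_rrt))
  for (i in seq_along(reference$shmp_rrt)) {
    shmp_hit[i] <- any(match_rrt(rrts, reference$shmp_rrt[i], rrt_tol) &
                         pks$snr >= min_snr)
  }
  runs <- rle(shmp_hit)
  max_run <- if (length(runs$lengths)) {
    m <- runs$lengths[runs$values]
    if (length(m)) max(m) else 0L
  } else 0L
  shmp_detected <- max_run >= min_shmp_run
  list(
    positive = any(matches$matched) || shmp_detected,
    matches = matches,
    shmp_peaks_matched = sum(shmp_hit),
    shmp_detected = shmp_detected,
    ortho_rt = ortho_rt
  )
}

#' Screen a conductometric trace for (poly)phosphate additives
#'
#' Detects peaks, anchors relative retention times on the orthophosphate
#' peak (the first detected peak), and matches the additive species (pyro-,
#' tri-, trimetaphosphate) and the SHMP envelope against a reference built
#' from a run spiked at the 200 µg/g screening cut-off. The sample is
#' screening-positive iff at least one additive species matches within the
#' RRT tolerance at `min_snr`, or at least `min_shmp_run` consecutive SHMP
#' envelope peaks match. When a list of replicate traces is supplied
#' (duplicate injections), every replicate must be positive.
#'
#' @param trace An SCD `phos_trace`, or a list of replicate traces.
#' @param reference An `rrt_reference`.
#' @param min_snr Minimum S/N (default 3, the screening confirmative level).
#' @param rrt_tol RRT tolerance as a relative deviation (default 0.025).
#' @param min_shmp_run Consecutive envelope-peak matches required to call
#'   the SHMP envelope (default 3).
#' @return A `scd_screen` list: `positive`, species `matches` tibble,
#'   `shmp_peaks_matched`, `shmp_detected`, `ortho_rt`, `n_replicates`.
#' @export
screen_scd <- function(trace, reference, min_snr = 3, rrt_tol = 0.025,
                       min_shmp_run = 3L) {
  traces <- if (is.data.frame(trace)) list(trace) else trace
  res <- purrr::map(traces, screen_one, reference = reference,
                    min_snr = min_snr, rrt_tol = rrt_tol,
                    min_shmp_run = min_shmp_run)
  out <- res[[1]]
  if (length(res) > 1L) {
    for (r in res[-1]) {
      out$positive <- out$positive && r$positive
      out$matches$matched <- out$matches$matched & r$matches$matched
      out$shmp_detected <- out$shmp_detected && r$shmp_detected
      out$shmp_peaks_matched <- min(out$shmp_peaks_matched,
                                    r$shmp_peaks_matched)
    }
    out$positive <- any(out$matches$matched) || out$shmp_detected
  }
  out$n_replicates <- length(res)
  class(out) <- "scd_screen"
  out
}

#' @export
print.scd_screen <- function(x, ...) {
  cat(sprintf("<scd_screen: %s; species matched: %s; SHMP envelope: %s (%d peaks)>\n",
              if (x$positive) "POSITIVE" else "negative",
              if (any(x$matches$matched))
                paste(x$matches$name[x$matches$matched], collapse = ", ")
              else "none",
              if (x$shmp_detected) "detected" else "ND",
              x$shmp_peaks_matched))
  invisible(x)
}

#' False-positive rate check for the screening method
#'
#' Validation rule: fewer than 5% of fortified samples may fall below the
#' blanks' mean signal plus three standard deviations.
#'
#' @param blank_signals Numeric, signals of >= 2 blank samples.
#' @param fortified_signals Numeric, signals of fortified samples.
#' @return A list: `fraction` (fortified below the blank threshold),
#'   `threshold`, `pass` (`fraction < 0.05`).
#' @export
false_positive_check <- function(blank_signals, fortified_signals) {
  if (length(blank_signals) < 2L) {
    stop("need at least 2 blank signals", call. = FALSE)
  }
  if (length(fortified_signals) == 0L) {
    stop("no fortified signals supplied", call. = FALSE)
  }
  thr <- mean(blank_signals) + 3 * stats::sd(blank_signals)
  frac <- mean(fortified_signals < thr)
  list(fraction = frac, threshold = thr, pass = frac < 0.05)
}

#' Instrumental linearity of a calibration series
#'
#' Ordinary least-squares fit of response on concentration.
#'
#' @param data Data frame with columns `conc` and `response` (or supply
#'   `levels`/`responses` directly).
#' @param levels,responses Optional numeric vectors overriding `data`.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
linearity <- function(data = NULL, levels = NULL, responses = NULL) {
  if (is.null(levels)) {
    levels <- data$conc
    responses <- data$response
  }
  if (length(unique(levels)) < 3L) {
    stop("need at least 3 distinct concentration levels", call. = FALSE)
  }
  fit <- stats::lm(responses ~ levels)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n = length(levels)
  )
}
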