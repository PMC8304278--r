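# Baseline estimation, peak detection/integration and signal-to-noise.
#
# The baseline is a rolling median followed by a moving average: the median
# resists peaks occupying a minority of the window and, unlike a rolling
# minimum, is unbiased under noise, so baseline-subtracted peak-free regions
# have zero median. Peak bounds descend from the apex to 1% of the height or
# the first local minimum (valley split for overlapping peaks), and areas are
# trapezoidal integrals of the baseline-subtracted signal.

odd_window <- function(width_min, dt, n) {
  k <- max(3L, as.integer(round(width_min / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  min(k, if (n %% 2L == 0L) n - 1L else n)
}

#' Estimate a chromatographic baseline
#'
#' Rolling median (window `window` minutes) followed by a centred moving
#' average (half that window). Peaks much narrower than the window are
#' rejected; linear drift is tracked without bias.
#'
#' @param trace A `phos_trace` (or tibble with `time`/`intensity`).
#' @param window Baseline window in minutes; must be positive and smaller
#'   than the trace span.
#' @return A tibble `time`, `baseline`.
#' @export
estimate_baseline <- function(trace, window = 1.0) {
  span <- diff(range(trace$time))
  if (!is.numeric(window) || window <= 0) {
    stop("baseline window must be > 0", call. = FALSE)
  }
  if (window >= span) {
    stop("baseline window must be smaller than the trace span", call. = FALSE)
  }
  dt <- trace_dt(trace)
  n <- nrow(trace)
  k <- odd_window(window, dt, n)
  base <- as.numeric(stats::runmed(trace$intensity, k, endrule = "median"))
  ks <- odd_window(window / 2, dt, n)
  sm <- stats::filter(base, rep(1 / ks, ks), sides = 2)
  sm <- as.numeric(sm)
  # moving-average edges: fall back to the unsmoothed median
  sm[is.na(sm)] <- base[is.na(sm)]
  tibble::tibble(time = trace$time, baseline = sm)
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

trapz_area <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# robust noise scale of a baseline-subtracted signal
noise_sd <- function(y) {
  s <- stats::mad(y, center = stats::median(y))
  if (!is.finite(s)) 0 else s
}

# topographic prominence of each local maximum: height above the higher of
# the two valleys separating it from the nearest higher maxima (or edges)
peak_prominence <- function(ys, cand) {
  vapply(cand, function(i) {
    h <- ys[i]
    left <- h; right <- h
    j <- i
    lv <- h
    while (j > 1L) {
      j <- j - 1L
      lv <- min(lv, ys[j])
      if (ys[j] > h) break
    }
    left <- lv
    j <- i
    rv <- h
    n <- length(ys)
    while (j < n) {
      j <- j + 1L
      rv <- min(rv, ys[j])
      if (ys[j] > h) break
    }
    right <- rv
    h - max(left, right)
  }, numeric(1))
}

# bound of a peak: from the apex toward `limit`, stop at the first sample
# where the smoothed signal drops to floor_frac of the apex height; else
# the minimum of the smoothed signal on the way to `limit` (valley split)
bound_towards <- function(ys, apex, limit, floor_frac = 0.01) {
  if (apex == limit) return(apex)
  step <- sign(limit - apex)
  idx <- seq(apex, limit, by = step)
  seg <- ys[idx]
  floor_hit <- which(seg <= floor_frac * ys[apex])
  if (length(floor_hit)) return(idx[floor_hit[1]])
  idx[which.min(seg)]
}

#' Detect chromatographic peaks
#'
#' Finds local maxima of the baseline-subtracted, lightly smoothed signal
#' whose height clears `min_snr` times the robust noise scale and whose
#' bounds span at least `min_width` minutes. Overlapping peaks are split at
#' the valley between them. The reported `snr` uses noise re-estimated from
#' peak-free regions (see [snr()]).
#'
#' @inheritParams estimate_baseline
#' @param min_snr Minimum signal-to-noise ratio for a peak apex.
#' @param min_width Minimum peak width (bounds span), minutes.
#' @param baseline_window Passed to [estimate_baseline()].
#' @return A tibble of peaks: `apex_time`, `start_time`, `end_time`,
#'   `height`, `area`, `snr`, sorted by `apex_time`. Zero rows when nothing
#'   is found.
#' @export
detect_peaks <- function(trace, min_snr = 3, min_width = 0.05,
                         baseline_window = 1.0) {
  empty <- tibble::tibble(
    apex_time = numeric(0), start_time = numeric(0), end_time = numeric(0),
    height = numeric(0), area = numeric(0), snr = numeric(0)
  )
  bl <- estimate_baseline(trace, baseline_window)
  y <- trace$intensity - bl$baseline
  dt <- trace_dt(trace)
  n <- nrow(trace)
  ks <- odd_window(min_width, dt, n)
  ys <- as.numeric(stats::filter(y, rep(1 / ks, ks), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  sigma <- noise_sd(y)
  sigma_s <- noise_sd(ys)
  cand <- local_maxima(ys)
  # candidate gate on the smoothed signal (slight attenuation allowance),
  # then a prominence gate to reject noise ripples riding on real peaks
  if (sigma > 0) {
    cand <- cand[ys[cand] >= 0.8 * min_snr * sigma]
    prom <- peak_prominence(ys, cand)
    cand <- cand[prom >= pmax(3 * sigma_s, 0.3 * ys[cand])]
  } else {
    cand <- cand[ys[cand] > 0]
    prom <- peak_prominence(ys, cand)
    cand <- cand[prom >= 0.3 * ys[cand]]
  }
  if (length(cand) == 0L) return(empty)
  cand <- sort(cand)
  # valley-split bounds between neighbouring peaks, floor-clipped at 1% of
  # the smoothed apex height
  lo <- hi <- integer(length(cand))
  for (j in seq_along(cand)) {
    left_lim <- if (j == 1L) 1L else cand[j - 1L]
    right_lim <- if (j == length(cand)) n else cand[j + 1L]
    lo[j] <- bound_towards(ys, cand[j], left_lim)
    hi[j] <- bound_towards(ys, cand[j], right_lim)
  }
  # the apex is the smoothed-signal maximum; reading the raw height there
  # (rather than a raw-signal maximum nearby) avoids the upward bias a
  # max-over-noise refinement would add to low peaks. Sparse traces (XICs
  # with occasional jitter dropouts) can put the smoothed apex on a sample
  # far below the smoothed level; only then fall back to the neighbourhood
  # maximum.
  apex <- cand
  height <- vapply(apex, function(i) {
    h <- y[i]
    if (h < 0.7 * ys[i]) {
      h <- max(y[max(1L, i - 1L):min(n, i + 1L)])
    }
    h
  }, numeric(1))
  pk <- tibble::tibble(
    apex = apex, lo = pmin(lo, apex - 1L), hi = pmax(hi, apex + 1L),
    apex_time = trace$time[apex],
    height = height
  )
  pk <- pk[pk$lo >= 1L & pk$hi <= n, ]
  pk$start_time <- trace$time[pk$lo]
  pk$end_time <- trace$time[pk$hi]
  pk <- pk[pk$height > 0 & (pk$end_time - pk$start_time) >= min_width, ]
  if (nrow(pk) == 0L) return(empty)
  # second pass: the median baseline bulges under peaks, so snip the raw
  # signal across the (padded) peak spans and re-estimate the baseline on
  # the peak-free remainder
  inpeak <- rep(FALSE, n)
  for (r in seq_len(nrow(pk))) {
    pad <- max(3L, as.integer(round((pk$hi[r] - pk$lo[r]) / 4)))
    inpeak[max(pk$lo[r] - pad, 1L):min(pk$hi[r] + pad, n)] <- TRUE
  }
  ysnip <- trace$intensity
  runs <- rle(inpeak)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in which(runs$values)) {
    a0 <- max(starts[j] - 1L, 1L)
    b0 <- min(ends[j] + 1L, n)
    span <- starts[j]:ends[j]
    ysnip[span] <- stats::approx(
      x = trace$time[c(a0, b0)], y = trace$intensity[c(a0, b0)],
      xout = trace$time[span], rule = 2
    )$y
  }
  bl2 <- estimate_baseline(
    tibble::tibble(time = trace$time, intensity = ysnip), baseline_window
  )
  y <- trace$intensity - bl2$baseline
  pk$height <- vapply(pk$apex, function(i) {
    h <- y[i]
    if (h < 0.7 * ys[i]) h <- max(y[max(1L, i - 1L):min(n, i + 1L)])
    h
  }, numeric(1))
  pk$area <- vapply(seq_len(nrow(pk)), function(r) {
    idx <- pk$lo[r]:pk$hi[r]
    trapz_area(trace$time[idx], pmax(y[idx], 0))
  }, numeric(1))
  # noise from peak-free regions for the reported S/N
  free_sigma <- peak_free_noise(trace$time, y, pk$apex_time,
                                pk$end_time - pk$start_time)
  # a noise scale indistinguishable from floating-point residue means a
  # noise-free signal: report the Inf sentinel
  eps <- 1e-9 * max(abs(y))
  pk$snr <- if (is.na(free_sigma) || free_sigma <= eps) {
    rep(Inf, nrow(pk))
  } else {
    pk$height / free_sigma
  }
  pk <- pk[pk$snr >= min_snr, c("apex_time", "start_time", "end_time",
                                "height", "area", "snr")]
  dplyr::arrange(pk, apex_time)
}

# noise scale from regions farther than ~3 peak-sd from every apex
# (peak sd approximated as width/4); NA when no free region exists
peak_free_noise <- function(time, y, apexes, widths) {
  if (length(apexes) == 0L) return(noise_sd(y))
  free <- rep(TRUE, length(time))
  for (j in seq_along(apexes)) {
    sd_t <- max(widths[j] / 4, 1e-6)
    free <- free & abs(time - apexes[j]) > 3 * sd_t
  }
  if (sum(free) < 10L) return(NA_real_)
  noise_sd(y[free])
}

#' Signal-to-noise ratio of a detected peak
#'
#' Height divided by the robust noise scale (1.4826 x median absolute
#' deviation) of the baseline-subtracted signal in peak-free regions of the
#' trace. Noise-free signals report `Inf`.
#'
#' @param peak One-row tibble as returned by [detect_peaks()].
#' @param trace The trace the peak was detected in.
#' @inheritParams estimate_baseline
#' @return Ratio (possibly `Inf`).
#' @export
snr <- function(peak, trace, window = 1.0) {
  stopifnot(nrow(peak) == 1L)
  bl <- estimate_baseline(trace, window)
  y <- trace$intensity - bl$baseline
  s <- peak_free_noise(trace$time, y, peak$apex_time,
                       peak$end_time - peak$start_time)
  if (is.na(s)) {
    stop("no peak-free region available to estimate noise", call. = FALSE)
  }
  if (s <= 1e-9 * max(abs(y))) return(Inf)
  peak$height / s
}

#' Summed area of the SHMP multi-peak envelope
#'
#' Sodium hexametaphosphate elutes as an envelope of many partially
#' overlapping peaks; its response is taken as the sum of the areas of the
#' first ten peaks (by elution order) inside the envelope window. Fewer than
#' ten available peaks are summed as-is and flagged.
#'
#' @param peaks Peak tibble from [detect_peaks()].
#' @param window Length-2 numeric, time window (min) of the envelope.
#' @param n_max Number of leading peaks to sum (default 10).
#' @return A list with `area`, `count` and `complete` (TRUE iff `n_max`
#'   peaks were available).
#' @export
shmp_envelope_area <- function(peaks, window = c(14, 28), n_max = 10L) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  inside <- peaks[peaks$apex_time >= window[1] &
                    peaks$apex_time <= window[2], ]
  inside <- dplyr::arrange(inside, apex_time)
  use <- utils::head(inside, n_max)
  list(area = sum(use$area), count = nrow(use),
       complete = nrow(use) >= n_max)
}
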