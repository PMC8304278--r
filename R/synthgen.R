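# Seeded synthetic-data generator: conductometric traces, HRMS scan sets,
# calibration series and validation batches with known ground truth.
#
# The generator emulates the study conditions: Gaussian chromatographic
# peaks at the database retention times (sigma 0.08 min, consistent with
# baseline-resolved peaks 1-2 min apart), a natural orthophosphate
# background in the 30-1300 µg/g range, an optional matrix interferent at
# 6.95 min, a ten-peak SHMP envelope on a documented 14-27.5 min grid with
# geometrically decaying areas (ratio 0.85), and centroid m/z jitter at the
# ppm scale. Conductometric response is proportional to the P2O5-equivalent
# amount; the sensitivity constant is calibrated so a 200 µg/g single-species
# spike sits near S/N 10 at default noise.

SCD_SENSITIVITY <- 0.0625   # height units per µg/g P2O5-equivalent
SHMP_FIRST_PEAK_GAIN <- 1.5 # envelope first-peak gain relative to a species
SHMP_DECAY <- 0.85          # geometric area decay across the envelope
SHMP_RT_GRID <- seq(14, by = 1.5, length.out = 10)
HRMS_SENSITIVITY <- 100     # intensity units per µg/g at the peak apex
INTERFERENT_RT <- 6.95

#' Specify a synthetic sample
#'
#' @param matrix_type `"meat"`, `"fish"`, `"dairy"` or `"blank"`.
#' @param spikes Named numeric, species name -> µg/g (free-acid basis).
#' @param shmp_spike SHMP spike, µg/g expressed as P2O5 (the commercial
#'   standard's denomination).
#' @param natural_ortho Natural orthophosphate background, µg/g; defaults
#'   per matrix (meat 850, fish 950, dairy 550, blank 400), inside the
#'   30-1300 µg/g natural range.
#' @param interferent Add the 6.95-min matrix interferent peak?
#' @param baseline_sd,proportional_sd,drift Noise model: additive white
#'   noise SD (signal units), proportional noise SD (fraction of signal),
#'   baseline drift slope (units/min).
#' @param peak_width_sd Gaussian peak sigma, minutes.
#' @param mz_jitter_ppm Centroid m/z jitter SD, ppm.
#' @param seed Integer seed fixing all randomness.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(matrix_type = c("blank", "meat", "fish", "dairy"),
                           spikes = numeric(0), shmp_spike = 0,
                           natural_ortho = NULL, interferent = FALSE,
                           baseline_sd = 1, proportional_sd = 0.01,
                           drift = 0, peak_width_sd = 0.08,
                           mz_jitter_ppm = 2, seed = 1L) {
  matrix_type <- match.arg(matrix_type)
  spikes <- unlist(spikes)
  if (is.null(spikes)) spikes <- numeric(0)
  if (is.null(natural_ortho)) {
    natural_ortho <- c(blank = 400, meat = 850, fish = 950,
                       dairy = 550)[[matrix_type]]
  }
  stopifnot(all(spikes >= 0), shmp_spike >= 0, natural_ortho >= 0,
            peak_width_sd > 0, baseline_sd >= 0)
  if (length(spikes)) {
    bad <- setdiff(names(spikes), phosphate_species()$name)
    if (length(bad)) stop("unknown spike species: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(matrix_type = matrix_type, spikes = spikes, shmp_spike = shmp_spike,
         natural_ortho = natural_ortho, interferent = interferent,
         baseline_sd = baseline_sd, proportional_sd = proportional_sd,
         drift = drift, peak_width_sd = peak_width_sd,
         mz_jitter_ppm = mz_jitter_ppm, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# species amounts implied by a spec, on the µg/g (free acid) scale, with
# the natural orthophosphate background folded into the ortho amount
spec_amounts <- function(spec) {
  amounts <- spec$spikes
  ortho_nat <- spec$natural_ortho
  if ("orthophosphate" %in% names(amounts)) {
    amounts[["orthophosphate"]] <- amounts[["orthophosphate"]] + ortho_nat
  } else if (ortho_nat > 0) {
    amounts <- c(amounts, orthophosphate = ortho_nat)
  }
  amounts
}

gaussian_peak <- function(t, rt, height, sigma) {
  height * exp(-(t - rt)^2 / (2 * sigma^2))
}

#' Generate a synthetic conductometric trace
#'
#' Builds an SCD trace (0-30 min, 0.01-min sampling) with Gaussian peaks at
#' the database retention times for each spiked species, response
#' proportional to the P2O5-equivalent amount; an SHMP spike renders the
#' ten-peak envelope on the default retention-time grid with geometrically
#' decaying heights. Ground truth (per-peak species, retention time, height
#' and expected S/N) is attached as the `"ground_truth"` attribute.
#'
#' @param spec A [synthetic_spec()].
#' @param t_range Time range, minutes.
#' @param dt Sampling interval, minutes.
#' @return A `phos_trace` with a `ground_truth` attribute.
#' @export
generate_scd_trace <- function(spec, t_range = c(0, 30), dt = 0.01) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::local_seed(spec$seed)
  t <- seq(t_range[1], t_range[2], by = dt)
  db <- phosphate_species()
  sig <- numeric(length(t))
  gt <- list()
  amounts <- spec_amounts(spec)
  for (nm in names(amounts)) {
    sp <- db[db$name == nm, ]
    h <- SCD_SENSITIVITY * p2o5_equivalent(amounts[[nm]], sp)
    sig <- sig + gaussian_peak(t, sp$expected_rt, h, spec$peak_width_sd)
    gt[[length(gt) + 1L]] <- tibble::tibble(
      species = nm, rt = sp$expected_rt, amount = amounts[[nm]],
      height = h, true_snr = if (spec$baseline_sd > 0)
        h / spec$baseline_sd else Inf
    )
  }
  if (spec$shmp_spike > 0) {
    h1 <- SCD_SENSITIVITY * SHMP_FIRST_PEAK_GAIN * spec$shmp_spike
    for (i in seq_along(SHMP_RT_GRID)) {
      h <- h1 * SHMP_DECAY^(i - 1)
      sig <- sig + gaussian_peak(t, SHMP_RT_GRID[i], h, spec$peak_width_sd)
      gt[[length(gt) + 1L]] <- tibble::tibble(
        species = sprintf("shmp_peak_%02d", i), rt = SHMP_RT_GRID[i],
        amount = spec$shmp_spike, height = h,
        true_snr = if (spec$baseline_sd > 0) h / spec$baseline_sd else Inf
      )
    }
  }
  if (spec$interferent) {
    h <- 5 * spec$baseline_sd + 5  # always clearly detectable
    sig <- sig + gaussian_peak(t, INTERFERENT_RT, h, spec$peak_width_sd)
    gt[[length(gt) + 1L]] <- tibble::tibble(
      species = "interferent", rt = INTERFERENT_RT, amount = NA_real_,
      height = h, true_snr = if (spec$baseline_sd > 0)
        h / spec$baseline_sd else Inf
    )
  }
  noise <- stats::rnorm(length(t), 0, spec$baseline_sd) +
    sig * stats::rnorm(length(t), 0, spec$proportional_sd) +
    spec$drift * t
  tr <- new_trace(t, sig + noise, channel = "SCD",
                  sample_id = sprintf("synthetic-%s-seed%d",
                                      spec$matrix_type, spec$seed))
  attr(tr, "ground_truth") <- dplyr::bind_rows(gt)
  tr
}

#' Generate a synthetic HRMS scan set
#'
#' Full scans carry centroids at each present species' deprotonated-
#' precursor m/z (Gaussian elution profile, ppm-scale m/z jitter) plus a
#' log-normal chemical background at every database precursor and fragment
#' mass; DIA scans (1 Th isolation, one window per database precursor each
#' cycle) carry the confirmation fragments at `fragment_efficiency` times
#' the precursor intensity. An `interconversion` fraction re-emits the
#' pyrophosphate anion at the ortho- and triphosphate retention times,
#' emulating in-source transformation.
#'
#' @param spec A [synthetic_spec()].
#' @param t_range Acquisition window, minutes.
#' @param dt Cycle time, minutes.
#' @param fragment_efficiency Fragment-to-precursor intensity ratio in DIA.
#' @param interconversion Fraction of the pyrophosphate-ion signal re-emitted
#'   at the ortho-/triphosphate retention times (0 disables).
#' @param background Median of the log-normal background intensity (sdlog
#'   0.3) at each monitored m/z; the ground-truth `true_snr` is the apex
#'   intensity over this level, a conservative scale for the measured S/N.
#' @return A `scan_set` with a `ground_truth` attribute (species, rt,
#'   amount, apex intensity, true S/N vs background).
#' @export
generate_hrms_scanset <- function(spec, t_range = c(4, 24), dt = 0.05,
                                  fragment_efficiency = 0.3,
                                  interconversion = 0,
                                  background = 50) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::local_seed(spec$seed + 1L)
  times <- seq(t_range[1], t_range[2], by = dt)
  db <- phosphate_species()
  amounts <- spec_amounts(spec)
  # internal standard is added to every extract at a fixed level
  if (!("internal_standard" %in% names(amounts))) {
    amounts <- c(amounts, internal_standard = 5)
  }
  # long-chain content of an SHMP spike: the envelope species share the
  # spiked amount with the same geometric decay as the SCD envelope
  if (spec$shmp_spike > 0) {
    lc <- longchain_species()
    w <- SHMP_DECAY^(seq_along(lc) - 1)
    w <- w / sum(w)
    for (k in seq_along(lc)) {
      prev <- if (lc[k] %in% names(amounts)) amounts[[lc[k]]] else 0
      amounts[[lc[k]]] <- prev + spec$shmp_spike * w[k]
    }
  }
  present <- db[db$name %in% names(amounts), ]
  apex_int <- stats::setNames(
    HRMS_SENSITIVITY * unlist(amounts[present$name]), present$name
  )
  jit <- function(mz, n = length(mz)) {
    mz * (1 + stats::rnorm(n, 0, spec$mz_jitter_ppm) * 1e-6)
  }
  profile <- function(nm, t) {
    sp <- db[db$name == nm, ]
    gaussian_peak(t, sp$expected_rt, apex_int[[nm]], spec$peak_width_sd)
  }
  fs_scan <- function(t) {
    mzs <- jit(db$precursor_mz)           # background at every precursor
    ints <- background * stats::rlnorm(nrow(db), 0, 0.3)
    for (nm in present$name) {
      v <- profile(nm, t)
      if (v > background / 10) {
        mzs <- c(mzs, jit(db$precursor_mz[db$name == nm]))
        ints <- c(ints, v)
      }
    }
    if (interconversion > 0 && "pyrophosphate" %in% present$name) {
      pyro <- db[db$name == "pyrophosphate", ]
      for (rt_other in db$expected_rt[db$name %in%
                                      c("orthophosphate", "triphosphate")]) {
        v <- gaussian_peak(t, rt_other,
                           interconversion * apex_int[["pyrophosphate"]],
                           spec$peak_width_sd)
        if (v > background / 10) {
          mzs <- c(mzs, jit(pyro$precursor_mz))
          ints <- c(ints, v)
        }
      }
    }
    o <- order(mzs)
    list(mz = mzs[o], intensity = ints[o])
  }
  dia_scan <- function(t, sp_row) {
    frs <- sp_row$fragment_mzs[[1]]
    mzs <- if (length(frs)) jit(frs) else numeric(0)
    ints <- background * stats::rlnorm(length(frs), 0, 0.3)
    nm <- sp_row$name
    if (nm %in% present$name && length(frs)) {
      v <- fragment_efficiency * profile(nm, t)
      if (v > background / 10) {
        mzs <- c(mzs, jit(frs))
        ints <- c(ints, rep(v, length(frs)))
      }
    }
    o <- order(mzs)
    list(mz = mzs[o], intensity = ints[o])
  }
  rows <- vector("list", length(times) * (1L + nrow(db)))
  k <- 0L
  for (t in times) {
    fs <- fs_scan(t)
    k <- k + 1L
    rows[[k]] <- list(time = t, mode = "FS", iso_center = NA_real_,
                      iso_width = NA_real_, mz = fs$mz,
                      intensity = fs$intensity)
    for (r in seq_len(nrow(db))) {
      d <- dia_scan(t, db[r, ])
      k <- k + 1L
      rows[[k]] <- list(time = t, mode = "DIA",
                        iso_center = db$precursor_mz[r], iso_width = 1,
                        mz = d$mz, intensity = d$intensity)
    }
  }
  scans <- tibble::tibble(
    time = vapply(rows, `[[`, numeric(1), "time"),
    mode = vapply(rows, `[[`, character(1), "mode"),
    iso_center = vapply(rows, `[[`, numeric(1), "iso_center"),
    iso_width = vapply(rows, `[[`, numeric(1), "iso_width"),
    mz = lapply(rows, `[[`, "mz"),
    intensity = lapply(rows, `[[`, "intensity")
  )
  ss <- new_scan_set(scans)
  gt <- tibble::tibble(
    species = present$name,
    rt = present$expected_rt,
    amount = unlist(amounts[present$name]),
    apex_intensity = unname(apex_int[present$name]),
    true_snr = unname(apex_int[present$name]) / background
  )
  attr(ss, "ground_truth") <- gt
  attr(ss, "sample_id") <- sprintf("synthetic-%s-seed%d",
                                   spec$matrix_type, spec$seed)
  ss
}

#' Generate a labelled validation batch
#'
#' Blank and fortified replicate traces for the screening-validation
#' experiments (specificity, false-positive rule, detection capability at
#' the cut-off).
#'
#' @param spec Base [synthetic_spec()] describing the matrix and noise.
#' @param n_blanks,n_fortified Replicate counts (>= 1).
#' @param spike_level Fortification level, µg/g (default 200, the screening
#'   cut-off).
#' @param species Species used to fortify.
#' @return Tibble with columns `label` (`"blank"`/`"fortified"`), `replicate`
#'   and `trace` (list-column of `phos_trace`).
#' @export
generate_validation_batch <- function(spec, n_blanks, n_fortified,
                                      spike_level = 200,
                                      species = "pyrophosphate") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_blanks < 1L || n_fortified < 1L) {
    stop("replicate counts must be >= 1", call. = FALSE)
  }
  make <- function(i, spike) {
    s <- spec
    s$seed <- spec$seed + i
    if (spike > 0) s$spikes <- c(s$spikes, stats::setNames(spike, species))
    generate_scd_trace(s)
  }
  blanks <- purrr::map(seq_len(n_blanks), make, spike = 0)
  forts <- purrr::map(n_blanks + seq_len(n_fortified), make,
                      spike = spike_level)
  tibble::tibble(
    label = rep(c("blank", "fortified"), c(n_blanks, n_fortified)),
    replicate = c(seq_len(n_blanks), seq_len(n_fortified)),
    trace = c(blanks, forts)
  )
}

#' Measured screening signal of a trace at a species' retention time
#'
#' Baseline-subtracted height at the expected retention time; the signal the
#' false-positive rule compares between blanks and fortified samples.
#'
#' @param trace A `phos_trace`.
#' @param rt Retention time to read, minutes.
#' @param window Half-window around `rt`, minutes.
#' @return Height in signal units.
#' @export
signal_at <- function(trace, rt, window = 0.2) {
  bl <- estimate_baseline(trace)
  y <- trace$intensity - bl$baseline
  sel <- abs(trace$time - rt) <= window
  max(y[sel])
}

#' Persist / load a synthetic-sample specification
#' @param spec A [synthetic_spec()].
#' @param path JSON path.
#' @return `read_synthetic_spec()` returns a `synthetic_spec`.
#' @export
write_synthetic_spec <- function(spec, path) {
  x <- unclass(spec)
  # named list keeps species names that auto_unbox would drop from a
  # length-one named vector
  x$spikes <- as.list(x$spikes)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_spec, x[c("matrix_type", "spikes", "shmp_spike",
                              "natural_ortho", "interferent", "baseline_sd",
                              "proportional_sd", "drift", "peak_width_sd",
                              "mz_jitter_ppm", "seed")])
}
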