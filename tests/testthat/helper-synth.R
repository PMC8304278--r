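# shared fixtures, built in code

# noise-free Gaussian trace on a zero baseline
gaussian_trace <- function(rts, heights, sigma = 0.1, t_range = c(0, 30),
                           dt = 0.01, offset = 0, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(t_range[1], t_range[2], by = dt)
  y <- rep(offset, length(t))
  for (i in seq_along(rts)) {
    y <- y + heights[i] * exp(-(t - rts[i])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  new_trace(t, y, channel = "SCD")
}

# hand-built scan set: one FS centroid stream at given m/z following a
# Gaussian elution profile, plus optional DIA fragments
tiny_scanset <- function(profiles, dia = list(), t_range = c(4, 14),
                         dt = 0.05, floor_int = 5) {
  times <- seq(t_range[1], t_range[2], by = dt)
  rows <- list()
  for (t in times) {
    mzs <- ints <- numeric(0)
    for (p in profiles) {
      v <- p$height * exp(-(t - p$rt)^2 / (2 * 0.08^2))
      mzs <- c(mzs, p$mz)
      ints <- c(ints, v + floor_int)
    }
    o <- order(mzs)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      time = t, mode = "FS", iso_center = NA_real_, iso_width = NA_real_,
      mz = list(mzs[o]), intensity = list(ints[o])
    )
    for (d in dia) {
      v <- d$height * exp(-(t - d$rt)^2 / (2 * 0.08^2))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        time = t, mode = "DIA", iso_center = d$iso_center, iso_width = 1,
        mz = list(sort(d$mz)), intensity = list(rep(v + floor_int,
                                                    length(d$mz)))
      )
    }
  }
  new_scan_set(dplyr::bind_rows(rows))
}

# reference RRT table from a cleanly spiked synthetic run
reference_from_spike <- function(seed = 101) {
  spec <- synthetic_spec(
    "blank",
    spikes = c(pyrophosphate = 200, triphosphate = 200,
               trimetaphosphate = 200),
    shmp_spike = 200, seed = seed
  )
  build_rrt_reference(generate_scd_trace(spec))
}
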