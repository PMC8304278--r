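# baseline, peak detection/integration, S/N, SHMP envelope rule

test_that("baseline tracks flat offsets and linear drift", {
  t <- seq(0, 20, 0.01)
  flat <- new_trace(t, rep(7, length(t)))
  bl <- estimate_baseline(flat)
  expect_true(all(abs(bl$baseline - 7) < 1e-9))
  # single Gaussian on an offset: baseline stays near the offset off-peak
  tr <- gaussian_trace(10, 50, offset = 4, t_range = c(0, 20))
  bl2 <- estimate_baseline(tr)
  off_peak <- abs(tr$time - 10) > 1
  expect_true(all(abs(bl2$baseline[off_peak] - 4) / 4 < 0.02))
  # noisy linear drift is recovered within the noise scale
  set.seed(1)
  y <- 2 + 0.5 * t + rnorm(length(t), 0, 0.5)
  bl3 <- estimate_baseline(new_trace(t, y))
  interior <- t > 1 & t < 19
  expect_lt(max(abs(bl3$baseline - (2 + 0.5 * t))[interior]), 0.5)
  expect_error(estimate_baseline(flat, window = 0), "> 0")
  expect_error(estimate_baseline(flat, window = 50), "span")
})

test_that("peak detection recovers Gaussian apexes and closed-form areas", {
  # zero trace: nothing found
  t <- seq(0, 10, 0.01)
  expect_equal(nrow(detect_peaks(new_trace(t, rep(0, length(t))))), 0L)
  # single noise-free Gaussian: area within 1% of A*sigma*sqrt(2*pi)
  tr <- gaussian_trace(5, 5, sigma = 0.1, t_range = c(0, 10))
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$area, 5 * 0.1 * sqrt(2 * pi), tolerance = 0.01)
  expect_equal(pk$height, 5, tolerance = 0.01)
  expect_true(pk$start_time < pk$apex_time, pk$apex_time < pk$end_time)
  # two Gaussians 2 min apart: both found, apexes within 0.02 min
  tr2 <- gaussian_trace(c(4, 6), c(5, 3), sigma = 0.1, t_range = c(0, 10))
  pk2 <- detect_peaks(tr2)
  expect_equal(nrow(pk2), 2L)
  expect_lt(max(abs(pk2$apex_time - c(4, 6))), 0.02)
})

test_that("detection is translation- and scale-equivariant", {
  base <- gaussian_trace(c(6, 9), c(20, 8), sigma = 0.1, t_range = c(0, 15),
                         noise_sd = 1, seed = 5)
  pk <- detect_peaks(base)
  shifted <- new_trace(base$time + 3, base$intensity)
  pk_sh <- detect_peaks(shifted)
  expect_equal(pk_sh$apex_time, pk$apex_time + 3, tolerance = 1e-9)
  scaled <- new_trace(base$time, base$intensity * 10)
  pk_sc <- detect_peaks(scaled)
  expect_equal(pk_sc$apex_time, pk$apex_time, tolerance = 1e-9)
  expect_equal(pk_sc$height, pk$height * 10, tolerance = 1e-6)
  expect_equal(pk_sc$snr, pk$snr, tolerance = 1e-6)
})

test_that("S/N estimates the injected height-to-noise ratio", {
  # Monte-Carlo: height 10, noise sd 1 -> snr near 10
  est <- vapply(1:100, function(s) {
    tr <- gaussian_trace(5, 10, sigma = 0.1, t_range = c(0, 10),
                         noise_sd = 1, seed = s)
    pk <- detect_peaks(tr)
    if (nrow(pk) == 0L) return(NA_real_)
    snr(pk[which.max(pk$height), ], tr)
  }, numeric(1))
  expect_true(all(!is.na(est)))
  expect_true(all(est > 10 * 0.6 & est < 10 * 1.6))
  expect_lt(abs(median(est) - 10) / 10, 0.2)
  # noise-free signal reports the Inf sentinel
  tr0 <- gaussian_trace(5, 10, t_range = c(0, 10))
  pk0 <- detect_peaks(tr0)
  expect_identical(snr(pk0, tr0), Inf)
  # height at 3x the noise sd sits at the screening cut-off
  est3 <- vapply(1:50, function(s) {
    tr <- gaussian_trace(5, 3, sigma = 0.1, t_range = c(0, 10),
                         noise_sd = 1, seed = 1000 + s)
    pks <- detect_peaks(tr, min_snr = 1.5)
    hit <- pks[abs(pks$apex_time - 5) < 0.2, ]
    if (nrow(hit) == 0L) return(NA_real_)
    snr(hit[1, ], tr)
  }, numeric(1))
  expect_lt(abs(median(est3, na.rm = TRUE) - 3), 1)
})

test_that("detection on generated traces has full recall and no false peaks", {
  # true S/N >= 5 peaks are all found, nothing spurious, over 50 seeds
  fdr_bad <- 0L
  miss <- 0L
  for (s in 1:50) {
    spec <- synthetic_spec(
      "meat",
      spikes = c(pyrophosphate = 200, triphosphate = 200,
                 trimetaphosphate = 200),
      seed = 3000 + s
    )
    tr <- generate_scd_trace(spec)
    gt <- attr(tr, "ground_truth")
    pk <- detect_peaks(tr, min_snr = 3)
    strong <- gt[gt$true_snr >= 5, ]
    for (rt in strong$rt) {
      if (!any(abs(pk$apex_time - rt) <= 0.1)) miss <- miss + 1L
    }
    for (at in pk$apex_time) {
      if (!any(abs(gt$rt - at) <= 0.1)) fdr_bad <- fdr_bad + 1L
    }
  }
  expect_equal(miss, 0L)
  expect_equal(fdr_bad, 0L)
})

test_that("SHMP envelope area follows the first-ten-peaks rule", {
  mk <- function(n) tibble::tibble(
    apex_time = seq(14.5, by = 1, length.out = n),
    start_time = seq(14.3, by = 1, length.out = n),
    end_time = seq(14.7, by = 1, length.out = n),
    height = rep(1, n), area = seq_len(n), snr = rep(10, n)
  )
  r10 <- shmp_envelope_area(mk(10))
  expect_equal(r10$area, 55)
  expect_equal(r10$count, 10L)
  expect_true(r10$complete)
  # 12 peaks: only the first ten by elution count
  r12 <- shmp_envelope_area(mk(12))
  expect_equal(r12$area, 55)
  # 3 peaks: partial sum, flagged incomplete
  r3 <- shmp_envelope_area(mk(3))
  expect_equal(r3$area, 6)
  expect_equal(r3$count, 3L)
  expect_false(r3$complete)
})
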