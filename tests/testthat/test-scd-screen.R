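# relative retention times, screening decisions, validation statistics

test_that("relative retention times divide by the ortho anchor", {
  expect_equal(relative_rt(5.9, 5.9), 1)
  expect_equal(relative_rt(9.0, 5.9), 9.0 / 5.9, tolerance = 1e-12)
  expect_equal(round(relative_rt(9.0, 5.9), 4), 1.5254)
  expect_error(relative_rt(9.0, 0), "orthophosphate reference")
})

test_that("RRT matching accepts 2.5% and rejects larger deviations", {
  expect_true(match_rrt(1.525, 1.525))
  expect_true(match_rrt(1.55, 1.5254))    # 1.6% off
  expect_false(match_rrt(1.60, 1.5254))   # 4.9% off
  # boundary behaviour, by construction
  expect_true(match_rrt(1.025, 1))
  expect_false(match_rrt(1.0251, 1))
  # the tolerance is relative, both sides
  expect_true(match_rrt(0.9757, 1.0005))
})

test_that("a spiked run yields a usable RRT reference", {
  ref <- reference_from_spike()
  expect_s3_class(ref, "rrt_reference")
  expect_equal(ref$species$name,
               c("pyrophosphate", "triphosphate", "trimetaphosphate"))
  expect_true(all(abs(ref$species$rrt - c(9.0, 11.8, 13.5) / 5.9) < 0.02))
  expect_length(ref$shmp_rrt, 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_rrt_reference(ref, f)
  back <- read_rrt_reference(f)
  expect_equal(back$species$rrt, ref$species$rrt, tolerance = 1e-6)
  expect_equal(back$shmp_rrt, ref$shmp_rrt, tolerance = 1e-6)
  expect_equal(back$ortho_rt, ref$ortho_rt, tolerance = 1e-6)
})

test_that("screening flags additive species and SHMP, not blanks", {
  ref <- reference_from_spike()
  # blank matrix: negative
  blank <- generate_scd_trace(synthetic_spec("meat", seed = 201))
  expect_false(screen_scd(blank, ref)$positive)
  # SHMP at the 200 ug/g cut-off: positive through the envelope
  shmp <- generate_scd_trace(synthetic_spec("fish", shmp_spike = 200,
                                            seed = 202))
  res <- screen_scd(shmp, ref)
  expect_true(res$positive)
  expect_true(res$shmp_detected)
  # pyrophosphate spike: positive through the species match
  pyro <- generate_scd_trace(synthetic_spec(
    "meat", spikes = c(pyrophosphate = 200), seed = 203))
  res2 <- screen_scd(pyro, ref)
  expect_true(res2$positive)
  expect_true(res2$matches$matched[res2$matches$name == "pyrophosphate"])
  # interferent at 6.95 min only: clearly separated, negative
  intf <- generate_scd_trace(synthetic_spec("dairy", interferent = TRUE,
                                            seed = 204))
  expect_false(screen_scd(intf, ref)$positive)
})

test_that("screening is invariant to uniform time-axis scaling", {
  ref <- reference_from_spike()
  tr <- generate_scd_trace(synthetic_spec(
    "meat", spikes = c(trimetaphosphate = 250), seed = 210))
  r1 <- screen_scd(tr, ref)
  stretched <- new_trace(tr$time * 1.15, tr$intensity)
  r2 <- screen_scd(stretched, ref)
  expect_equal(r2$positive, r1$positive)
  expect_equal(r2$matches$matched, r1$matches$matched)
})

test_that("positive rate is 1 at the cut-off and 0 on blanks over seeds", {
  ref <- reference_from_spike()
  pos <- neg <- 0L
  n <- 25L
  for (s in seq_len(n)) {
    spiked <- generate_scd_trace(synthetic_spec(
      "meat", spikes = c(pyrophosphate = 200), seed = 400 + s))
    if (screen_scd(spiked, ref)$positive) pos <- pos + 1L
    blank <- generate_scd_trace(synthetic_spec("meat", seed = 600 + s))
    if (screen_scd(blank, ref)$positive) neg <- neg + 1L
  }
  expect_equal(pos, n)
  expect_equal(neg, 0L)
})

test_that("duplicate injections must both be positive", {
  ref <- reference_from_spike()
  spiked <- generate_scd_trace(synthetic_spec(
    "meat", spikes = c(pyrophosphate = 200), seed = 501))
  blank <- generate_scd_trace(synthetic_spec("meat", seed = 502))
  expect_true(screen_scd(list(spiked, spiked), ref)$positive)
  expect_false(screen_scd(list(spiked, blank), ref)$positive)
})

test_that("the false-positive rule applies the blank + 3 sd threshold", {
  expect_error(false_positive_check(1, c(2, 3)), "at least 2")
  expect_error(false_positive_check(c(1, 1, 1), numeric(0)), "fortified")
  r <- false_positive_check(c(1, 1, 1), rep(100, 10))
  expect_equal(r$fraction, 0)
  expect_true(r$pass)
  # blanks mean 10 sd 2 -> threshold 16; exactly 1 of 20 below: 5%, fails
  blanks <- c(8, 10, 12)
  expect_equal(sd(blanks), 2)
  r20 <- false_positive_check(blanks, c(rep(100, 19), 14))
  expect_equal(r20$fraction, 0.05)
  expect_false(r20$pass)
  # 1 of 40 below: 2.5%, passes
  r40 <- false_positive_check(blanks, c(rep(100, 39), 14))
  expect_equal(r40$fraction, 0.025)
  expect_true(r40$pass)
})

test_that("linearity fits recover exact lines and flag degenerate input", {
  d <- tibble::tibble(conc = c(10, 25, 50, 75, 100), response = 2 * c(10, 25, 50, 75, 100))
  fit <- linearity(d)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  const <- tibble::tibble(conc = c(10, 25, 50), response = rep(5, 3))
  expect_equal(linearity(const)$r_squared, 0)
  expect_error(linearity(tibble::tibble(conc = c(1, 1, 1),
                                        response = 1:3)), "distinct")
})
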