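# XIC extraction, species confirmation, interconversion, fingerprint

test_that("XIC extraction copies exact-match centroids and respects ppm", {
  ss <- tiny_scanset(list(list(mz = 176.93595, rt = 9, height = 1000)),
                     floor_int = 0)
  x <- extract_xic(ss, 176.93595, tol_ppm = 5)
  prof <- 1000 * exp(-(x$time - 9)^2 / (2 * 0.08^2))
  expect_equal(x$intensity, prof, tolerance = 1e-9)
  # centroids 10 ppm away with 5 ppm tolerance: all-zero trace
  far <- extract_xic(ss, 176.93595 * (1 + 10e-6), tol_ppm = 5)
  expect_true(all(far$intensity == 0))
  expect_error(extract_xic(ss, 100, tol_ppm = 0), "> 0")
  expect_error(extract_xic(ss, 100, mode = "DIA"), "no DIA")
})

test_that("ppm jitter at 2 ppm loses under 5% of intensity at 5 ppm", {
  set.seed(7)
  n <- 100
  target <- 478.79071
  captured <- 0; total <- 0
  for (i in 1:n) {
    mzv <- target * (1 + rnorm(20, 0, 2e-6))
    iv <- rep(1, 20)
    total <- total + sum(iv)
    captured <- captured + sum(iv[abs(mzv - target) <= target * 5e-6])
  }
  expect_gt(captured / total, 0.95)
})

test_that("species confirmation needs RT match plus a co-eluting fragment", {
  pyro_mz <- 176.93595
  frag <- 96.96962
  ok <- tiny_scanset(
    list(list(mz = pyro_mz, rt = 9, height = 5000)),
    dia = list(list(mz = frag, rt = 9, height = 1500,
                    iso_center = pyro_mz))
  )
  rec <- confirm_species(ok, "pyrophosphate")
  expect_true(rec$confirmed)
  expect_lt(abs(rec$matched_rt - 9), 0.1)
  expect_lt(abs(rec$mass_error_ppm), 1)
  expect_true(any(abs(rec$fragments_confirmed[[1]] - frag) < 0.001))
  # precursor without any DIA fragment: not confirmed
  no_frag <- tiny_scanset(
    list(list(mz = pyro_mz, rt = 9, height = 5000)),
    dia = list(list(mz = frag, rt = 9, height = 0,
                    iso_center = pyro_mz))
  )
  rec2 <- confirm_species(no_frag, "pyrophosphate")
  expect_false(rec2$confirmed)
  expect_match(rec2$note, "fragment|DIA")
  # precursor only at the orthophosphate RT: wrong RT, not confirmed
  wrong_rt <- tiny_scanset(list(list(mz = pyro_mz, rt = 5.9, height = 5000)))
  rec3 <- confirm_species(wrong_rt, "pyrophosphate")
  expect_false(rec3$confirmed)
})

test_that("confirmation is monotone in the tolerances", {
  spec <- synthetic_spec("meat", spikes = c(pyrophosphate = 80), seed = 17)
  ss <- generate_hrms_scanset(spec, t_range = c(5, 13))
  got <- vapply(c(0.2, 0.5, 0.8), function(tol) {
    confirm_species(ss, "pyrophosphate", rt_tol = tol)$confirmed
  }, logical(1))
  expect_true(all(diff(got) >= 0))
  got_ppm <- vapply(c(3, 5, 10), function(ppm) {
    confirm_species(ss, "pyrophosphate", tol_ppm = ppm)$confirmed
  }, logical(1))
  expect_true(all(diff(got_ppm) >= 0))
})

test_that("cross-RT signal is attributed to in-source interconversion", {
  pyro_mz <- 176.93595
  frag <- 96.96962
  # pyrophosphate ion at its own RT and at the ortho RT: confirmed at 9.0,
  # the 5.9 peak excluded and noted
  both <- tiny_scanset(
    list(list(mz = pyro_mz, rt = 9, height = 5000),
         list(mz = pyro_mz + 0.5, rt = 5.9, height = 2000)),
    dia = list(list(mz = frag, rt = 9, height = 1500,
                    iso_center = pyro_mz))
  )
  # fold the 5.9-min emission onto the same m/z
  both$mz <- lapply(both$mz, function(m) {
    m[abs(m - (pyro_mz + 0.5)) < 1e-6] <- pyro_mz
    sort(m)
  })
  rec <- confirm_species(both, "pyrophosphate")
  recs <- resolve_interconversion(
    tibble::as_tibble(rec), both
  )
  expect_true(recs$confirmed)
  expect_equal(round(recs$matched_rt, 1), 9)
  expect_match(recs$note, "interconversion")
  expect_match(recs$note, "orthophosphate")
  # ion only at the triphosphate RT: unconfirmed, flagged as its in-source
  # fragment
  only_tri <- tiny_scanset(list(list(mz = pyro_mz, rt = 11.8,
                                     height = 5000)),
                           t_range = c(4, 14))
  rec2 <- confirm_species(only_tri, "pyrophosphate")
  recs2 <- resolve_interconversion(tibble::as_tibble(rec2), only_tri)
  expect_false(recs2$confirmed)
  expect_match(recs2$note, "in-source fragment of triphosphate")
  # no cross-RT signal: records unchanged
  clean <- tiny_scanset(list(list(mz = pyro_mz, rt = 9, height = 5000)))
  rec3 <- confirm_species(clean, "pyrophosphate")
  recs3 <- resolve_interconversion(tibble::as_tibble(rec3), clean)
  expect_equal(recs3$note, rec3$note)
})

test_that("generator interconversion shows the pyro ion at three RTs", {
  spec <- synthetic_spec("meat", spikes = c(pyrophosphate = 100), seed = 23)
  ss <- generate_hrms_scanset(spec, interconversion = 0.2)
  xic <- extract_xic(ss, phosphate_species()$precursor_mz[
    phosphate_species()$name == "pyrophosphate"])
  pks <- detect_peaks(xic, min_snr = 3, min_width = 0.1,
                      baseline_window = 2)
  for (rt in c(5.9, 9.0, 11.8)) {
    expect_true(any(abs(pks$apex_time - rt) <= 0.2),
                label = sprintf("peak near %.1f min", rt))
  }
})

test_that("long-chain fingerprint equals the spiked set", {
  # blank: empty fingerprint
  blank <- generate_hrms_scanset(synthetic_spec("blank", seed = 31),
                                 t_range = c(13, 23))
  expect_length(fingerprint_longchain(blank), 0)
  # only pentaphosphate present
  penta <- generate_hrms_scanset(
    synthetic_spec("blank", spikes = c(pentaphosphate = 60), seed = 37),
    t_range = c(13, 23)
  )
  expect_equal(fingerprint_longchain(penta), "pentaphosphate")
  # SHMP-treated: all six long chains, in elution order
  shmp <- generate_hrms_scanset(
    synthetic_spec("fish", shmp_spike = 300, seed = 41), t_range = c(13, 23)
  )
  fp <- fingerprint_longchain(shmp)
  db <- phosphate_species()
  expect_equal(fp, db$name[order(db$expected_rt)][db$name[order(db$expected_rt)] %in%
                                                    longchain_species()])
})
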