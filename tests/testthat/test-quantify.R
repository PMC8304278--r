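# calibration fitting, LOD/LOQ, censored back-calculation, recovery, CV

test_that("calibration fits recover exact lines with zero intercept SD", {
  d <- tibble::tibble(conc = c(1, 2, 4, 8, 16), response = 3 * c(1, 2, 4, 8, 16) + 1)
  fit <- fit_calibration(d)
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$sd_intercept, 0, tolerance = 1e-7)
  expect_error(fit_calibration(tibble::tibble(conc = c(1, 2), response = c(1, 2))),
               "3 distinct")
  expect_error(fit_calibration(tibble::tibble(conc = c(1, 2, 3),
                                              response = c(3, 2, 1))),
               "positive")
})

test_that("intercept SD matches the closed-form OLS standard error", {
  x <- c(1, 2, 3, 4, 5)
  resid <- c(0.02, -0.05, 0.01, 0.04, -0.02)  # fixed residual pattern
  y <- 2 * x + 0.5 + resid
  fit <- fit_calibration(tibble::tibble(conc = x, response = y))
  # closed form: s^2 = SSE/(n-2); se(b0) = s * sqrt(1/n + xbar^2/Sxx)
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  sse <- sum((y - a - b * x)^2)
  s <- sqrt(sse / (length(x) - 2))
  se0 <- s * sqrt(1 / length(x) + mean(x)^2 / sum((x - mean(x))^2))
  expect_equal(fit$sd_intercept, se0, tolerance = 1e-9)
  expect_equal(fit$slope, b, tolerance = 1e-9)
})

test_that("tidy and glance expose the fit in broom style", {
  d <- tibble::tibble(conc = c(1, 2, 3, 4), response = c(2.1, 3.9, 6.2, 7.8))
  fit <- fit_calibration(d, species = "pyrophosphate")
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(fit)
  expect_equal(gl$species, "pyrophosphate")
  expect_equal(gl$lod / gl$loq, 3.3 / 10, tolerance = 1e-12)
})

test_that("LOD and LOQ follow 3.3/10 x SD over slope", {
  d <- tibble::tibble(conc = c(0, 1, 2, 3), response = c(0, 1, 2, 3))
  fit <- fit_calibration(d)
  fit$sd_intercept <- 0.03
  fit$slope <- 1
  expect_equal(lod(fit), 0.099, tolerance = 1e-12)
  expect_equal(loq(fit), 0.300, tolerance = 1e-12)
  fit$sd_intercept <- 0
  expect_equal(lod(fit), 0)
  # ratio fixed for any valid curve, here with genuine noise
  set.seed(11)
  noisy <- tibble::tibble(conc = c(1, 2, 4, 8, 16))
  noisy$response <- 5 * noisy$conc + rnorm(5, 0, 0.3)
  nf <- fit_calibration(noisy)
  expect_equal(loq(nf) / lod(nf), 10 / 3.3, tolerance = 1e-12)
})

test_that("fitted slopes recover the generating slope across seeds", {
  # parameter recovery at known noise: b within 2 theoretical SDs
  x <- c(10, 25, 50, 75, 100)
  sxx <- sum((x - mean(x))^2)
  sd_b <- 1 / sqrt(sxx)  # noise sd 1
  bad <- 0L
  for (s in 1:200) {
    set.seed(7000 + s)
    y <- 4 * x + rnorm(5, 0, 1)
    fit <- fit_calibration(tibble::tibble(conc = x, response = y))
    if (abs(fit$slope - 4) > 2 * sd_b) bad <- bad + 1L
  }
  # ~5% of draws may exceed 2 SDs
  expect_lt(bad / 200, 0.12)
})

test_that("back-calculation passes through the extraction algebra", {
  d <- tibble::tibble(conc = c(1, 2, 4, 8), response = 7 * c(1, 2, 4, 8))
  curve <- fit_calibration(d, species = "pyrophosphate")
  rec <- tibble::tibble(species = "pyrophosphate", confirmed = TRUE,
                        response = 7 * 5)  # response at 5 ug/mL
  q <- quantify_species(rec, curve)
  # 5 ug/mL x dilution 10 x 40 mL / 2 g = 1000 ug/g
  expect_equal(q$amount, 1000, tolerance = 1e-6)
  expect_equal(q$censoring, "quantified")
  # zero response: ND
  rec0 <- tibble::tibble(species = "pyrophosphate", confirmed = FALSE,
                         response = 0)
  expect_equal(quantify_species(rec0, curve)$censoring, "ND")
  # between LOD and LOQ: censored as <LOQ
  curve$sd_intercept <- 0.07  # LOD 0.033 ug/mL -> 6.6 ug/g sample scale
  mid_resp <- 7 * (lod(curve) + loq(curve)) / 2
  qmid <- quantify_species(tibble::tibble(species = "pyrophosphate",
                                          confirmed = TRUE,
                                          response = mid_resp), curve)
  expect_equal(qmid$censoring, "<LOQ")
  expect_true(is.na(qmid$amount))
  below <- quantify_species(tibble::tibble(species = "pyrophosphate",
                                           confirmed = TRUE,
                                           response = 7 * lod(curve) / 2),
                            curve)
  expect_equal(below$censoring, "<LOD")
  # no curve for a long-chain species: fingerprint only
  expect_error(quantify_species(tibble::tibble(species = "pentaphosphate",
                                               confirmed = TRUE,
                                               response = 100), NULL),
               "fingerprint only")
})

test_that("noise-free round trip through the generator scale is exact", {
  # concentration -> response (linear curve) -> back-calculated amount
  curve <- fit_calibration(tibble::tibble(conc = c(1, 5, 10, 20),
                                          response = 12 * c(1, 5, 10, 20)))
  for (conc in c(0.5, 2, 7.5)) {
    q <- quantify_species(tibble::tibble(species = "pyrophosphate",
                                         confirmed = TRUE,
                                         response = 12 * conc), curve)
    expect_equal(q$amount, conc * 200, tolerance = 1e-8)
  }
})

test_that("recovery and precision reproduce their defining arithmetic", {
  expect_equal(recovery(100, 100), 100)
  expect_equal(recovery(83, 100), 83)
  expect_error(recovery(50, 0), "zero")
  p <- precision(tibble::tibble(day = rep(1, 3), response = c(90, 100, 110)))
  expect_equal(p$intra_day_cv, 100 * sd(c(90, 100, 110)) / 100,
               tolerance = 1e-9)
  ident <- precision(tibble::tibble(day = rep(1:2, each = 3),
                                    response = rep(50, 6)))
  expect_equal(ident$intra_day_cv, 0)
  expect_equal(ident$inter_day_cv, 0)
  expect_error(precision(tibble::tibble(day = 1, response = 5)),
               "2 replicates")
})
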