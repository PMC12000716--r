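test_that("calibration table follows the generative law", {
  tab <- synthesize_noise_table(a = 1e-4, b = 0, means = c(1e-6, 4e-6))
  expect_equal(nrow(tab), 10)
  ref <- tab[tab$rate_hz == 1, ]
  expect_equal(ref$std, 1e-4 * sqrt(ref$mean))
  # quadrupling the fluence doubles the shot-noise std
  expect_equal(ref$std[2], 2 * ref$std[1])
  # variance scales linearly with acquisition rate
  t10 <- tab[tab$rate_hz == 10, ]
  expect_equal(t10$std^2, 10 * ref$std^2)
  # the floor clips small-fluence rows
  tf <- synthesize_noise_table(a = 1e-4, b = 5e-7, means = c(1e-6, 1))
  expect_equal(tf$std[tf$rate_hz == 1], c(5e-7, 1e-4))
})

test_that("noise lookup: exact at rows, linear between, rate-rescaled", {
  m <- noise_model(a = 1e-4, b = 0, means = c(1e-6, 2e-6, 4e-6))
  expect_equal(noise_std(m, 2e-6, 1), 1e-4 * sqrt(2e-6))
  mid <- noise_std(m, 3e-6, 1)
  expect_equal(mid, (1e-4 * sqrt(2e-6) + 1e-4 * sqrt(4e-6)) / 2)
  # same mean, 0.1 vs 10 Hz: std ratio sqrt(0.1/10) = 1/10
  expect_equal(noise_std(m, 2e-6, 0.1) / noise_std(m, 2e-6, 10), 0.1)
  # untabulated rate: reference table rescaled by sqrt(f/f_ref)
  expect_equal(noise_std(m, 2e-6, 2), sqrt(2) * noise_std(m, 2e-6, 1))
  # below-range means clamp to the lowest row; above-range means error
  expect_equal(noise_std(m, 1e-8, 1), 1e-4 * sqrt(1e-6))
  expect_error(noise_std(m, 1, 1), "above the calibration table")
  expect_error(noise_std(m, 0, 1), "positive")
})

test_that("CNR definition and algebra", {
  m <- noise_model(a = 1e-4, b = 0)
  expect_equal(cnr(1e-5, 1e-5, m, 1), 0)
  # equal stds sigma: CNR = |dphi| / (sigma sqrt(2))
  phi <- 1e-5
  sig <- noise_std(m, phi, 1)
  expect_equal(cnr(phi, phi * (1 - 1e-6), m, 1),
               phi * 1e-6 / (sig * sqrt(2)), tolerance = 1e-4)
  # CNR at 0.1 Hz is sqrt(10) x CNR at 1 Hz
  expect_equal(cnr(1e-5, 8e-6, m, 0.1),
               sqrt(10) * cnr(1e-5, 8e-6, m, 1))
  expect_error(cnr(0, 1e-5, m), "positive")
})

test_that("optimal SDD selection breaks ties towards depth", {
  cc <- structure(data.frame(sdd = c(2, 3, 4), cnr = c(0.1, 0.5, 0.2),
                             rate_hz = 1, orientation = "vertical"),
                  class = c("cnr_curve", "data.frame"))
  expect_equal(optimal_sdd(cc), 3)
  cc$cnr <- c(0.5, 0.2, 0.5)
  expect_equal(optimal_sdd(cc), 4)
  cc$cnr <- c(0.5, 0.4, 0.3)
  expect_equal(optimal_sdd(cc), 2)
  expect_equal(optimal_sdd(cc[1, ]), 2)
  expect_error(optimal_sdd(cc[0, ]), "empty")
})

test_that("cnr_curve wires readouts, noise and metadata together", {
  sc <- coarse_abdomen_sensitivity()
  m <- noise_model()
  cc <- cnr_curve(sc, m, rate = 1)
  expect_s3_class(cc, "cnr_curve")
  expect_equal(nrow(cc), 5)
  expect_equal(cc$adipose_thickness_cm, rep(2.4, 5))
  d <- sc[sc$tissue == "intestine", ]
  expect_equal(cc$contrast, abs(d$phiP - d$phi0))
  expect_true(all(cc$cnr >= 0))
  cc01 <- cnr_curve(sc, m, rate = 0.1)
  expect_equal(cc01$cnr, sqrt(10) * cc$cnr, tolerance = 1e-10)
})

test_that("coupling coefficient normalizes measurement to simulation", {
  expect_equal(coupling_coefficient(3e-6, 1.5e-6), 2)
  m <- noise_model(a = 1e-4, b = 0, kappa = 2)
  # contrast and noise scale together under kappa at the shot-noise law,
  # so CNR changes only through the sqrt: x2 contrast, x sqrt(2) noise
  m1 <- noise_model(a = 1e-4, b = 0, kappa = 1)
  expect_equal(cnr(1e-5, 8e-6, m, 1), sqrt(2) * cnr(1e-5, 8e-6, m1, 1),
               tolerance = 1e-3)
})
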