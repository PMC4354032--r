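test_that("chord-based geometry estimators invert the forward formulas", {
  expect_equal(patch_area_from_chord(0), 0)
  expect_equal(patch_area_from_chord(10), 78.54, tolerance = 1e-4)
  expect_error(patch_area_from_chord(-1), ">= 0")

  expect_equal(contact_angle_from_chord(0, 10), 0)
  expect_equal(contact_angle_from_chord(20, 10), pi / 2)
  expect_equal(contact_angle_from_chord(10, 10), pi / 6)
  expect_error(contact_angle_from_chord(21, 10), "diameter")

  expect_equal(total_area_from_fit(10, 0, 0), 4 * pi * 100)
  expect_equal(total_area_from_fit(10, pi / 3, 235.6), 1178.1, tolerance = 1e-4)

  # identity round trip: Lp = 2 R sin(theta)
  R <- 10.583; th <- pi / 3
  Lp <- 2 * R * sin(th)
  expect_equal(contact_angle_from_chord(Lp, R), th, tolerance = 1e-12)
  expect_equal(patch_area_from_chord(Lp), pi * R^2 * sin(th)^2,
               tolerance = 1e-12)
})

test_that("bridge-fraction estimator is exact on the forward intensity model", {
  N <- 4.9e5; A <- 1300; Ap <- 270
  for (x_b in c(0.05, 0.30, 0.60)) {
    ints <- intensity_model(x_b, N, A, Ap, T_C = 25)
    est <- bridge_fraction_from_intensities(ints, A, Ap)
    expect_equal(est, x_b, tolerance = 1e-10)
  }
  # a patch that is exactly two plain membranes carries no bridge excess
  ints <- intensity_model(0, N, A, Ap, T_C = 25)
  expect_equal(ints$Ip - ints$Ibg, 2 * (ints$Iv - ints$Ibg), tolerance = 1e-12)
  expect_equal(bridge_fraction_from_intensities(ints, A, Ap), 0)
  # invariance under common rescaling of background-subtracted intensities
  ints <- intensity_model(0.3, N, A, Ap, T_C = 25)
  half <- list(Iv = ints$Ibg + 0.5 * (ints$Iv - ints$Ibg),
               Ip = ints$Ibg + 0.5 * (ints$Ip - ints$Ibg), Ibg = ints$Ibg)
  expect_equal(bridge_fraction_from_intensities(half, A, Ap),
               bridge_fraction_from_intensities(ints, A, Ap), tolerance = 1e-12)
  expect_error(bridge_fraction_from_intensities(
    list(Iv = 1, Ip = 5, Ibg = 2), A, Ap), "Ibg")
})

test_that("intensity noise leaves the bridge-fraction estimator nearly unbiased", {
  N <- 4.9e5; A <- 1300; Ap <- 270
  set.seed(11)
  for (x_b in c(0.1, 0.3, 0.5)) {
    ints <- intensity_model(x_b, N, A, Ap, T_C = 25)
    nf <- 1000
    est <- vapply(seq_len(nf), function(i) {
      noisy <- list(Iv = ints$Iv * (1 + rnorm(1, 0, 0.02)),
                    Ip = ints$Ip * (1 + rnorm(1, 0, 0.02)),
                    Ibg = ints$Ibg * (1 + rnorm(1, 0, 0.02)))
      noisy$Iv <- max(noisy$Iv, noisy$Ibg)
      noisy$Ip <- max(noisy$Ip, noisy$Ibg)
      bridge_fraction_from_intensities(noisy, A, Ap)
    }, numeric(1))
    expect_lt(abs(mean(est) - x_b), 0.01)
  }
})

test_that("one-membrane subtraction variant overestimates the bridge signal", {
  N <- 4.9e5; A <- 1300; Ap <- 270
  ints <- intensity_model(0.3, N, A, Ap, T_C = 25)
  est1 <- bridge_fraction_from_intensities(ints, A, Ap, method = "one-membrane")
  expect_gt(est1, 0.3)
})

test_that("neglecting duplex brightness biases the estimate up by ~10%", {
  N <- 4.9e5; A <- 1300; Ap <- 270
  x_b <- 0.3; x_l <- 0.3
  ints <- intensity_model(x_b, N, A, Ap, T_C = 25,
                          noise = noise_spec(include_duplex_brightness = TRUE),
                          x_l = x_l)
  est <- bridge_fraction_from_intensities(ints, A, Ap)
  expect_gt(est, x_b)
  expect_lt(est, x_b * (1 + duplex_brightness_increment()) + 0.01)
})

test_that("full estimator round trip recovers the forward model", {
  p <- central_params()
  sim <- generate_pair_series(p, T_grid = c(10, 25, 40),
                              noise = noise_spec(sigma_R = 0, sigma_Lp = 0,
                                                 intensity_cv = 0))
  est <- estimate_observables(sim$observations)
  expect_equal(est$theta1_deg, sim$truth$theta_deg, tolerance = 1e-8)
  expect_equal(est$theta2_deg, sim$truth$theta_deg, tolerance = 1e-8)
  expect_equal(est$Ap_um2, sim$truth$Ap_um2, tolerance = 1e-8)
  expect_equal(est$A1_um2, sim$truth$A_um2, tolerance = 1e-8)
  expect_equal(est$x_b, sim$truth$x_b, tolerance = 1e-8)
})

test_that("coverage calibration cancels the slice thickness and recovers C", {
  # forward membrane intensity at two slice thicknesses -> same coverage
  C <- 2.7; d <- 0.076; R <- 12; rho <- 390; Id <- 5
  for (delta in c(0.4, 0.8)) {
    Iv <- Id + C * d * rho * 8 * R / delta
    expect_equal(coverage_from_calibration(Iv, Id, R, delta, C, d), rho,
                 tolerance = 1e-12)
  }
  expect_equal(coverage_from_calibration(5, 5, R, 0.5, C, d), 0)
  expect_error(coverage_from_calibration(4, 5, R, 0.5, C, d), "dark signal")
  # calibration series: fitted C within 1% under mild noise
  calib <- generate_calibration_series(C = 2.7, d = d, n_points = 25,
                                       noise = 0.02, seed = 3, delta = 0.5)
  expect_equal(fit_coverage_calibration(calib, Id = 5, d = d, delta = 0.5),
               2.7, tolerance = 0.01)
  # noise-free series is exactly linear
  calib0 <- generate_calibration_series(C = 2.7, d = d, n_points = 5,
                                        noise = 0, delta = 0.5)
  expect_equal(fit_coverage_calibration(calib0, Id = 5, d = d, delta = 0.5),
               2.7, tolerance = 1e-10)
  expect_equal(calib0$intensity[calib0$n == 0], 5)
})
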