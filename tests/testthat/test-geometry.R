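test_that("theta = 0 gives an untruncated sphere", {
  g <- geometry_at_angle(0, R0 = 10, L = 14.5)
  expect_equal(g$R, 10)
  expect_equal(g$A, 4 * pi * 100)
  expect_equal(g$Ap, 0)
  expect_equal(g$D, 20)
  expect_equal(g$V, 4 / 3 * pi * 1000)
  expect_equal(g$nu, 1)
})

test_that("60-degree geometry matches the closed forms", {
  g <- geometry_at_angle(pi / 3, R0 = 10, L = 14.5)
  expect_equal(g$R, 10 * (4 / 3.375)^(1 / 3), tolerance = 1e-12)
  expect_equal(g$R, 10.583, tolerance = 1e-4)
  expect_equal(g$Ap, pi * g$R^2 * 0.75, tolerance = 1e-12)
  expect_equal(g$Ap, 263.9, tolerance = 1e-3)
  expect_equal(g$D, g$R, tolerance = 1e-12)  # D = 2 R cos(60) = R
  expect_error(geometry_at_angle(pi / 2, 10), "pi/2")
  expect_error(geometry_at_angle(-0.1, 10), "pi/2")
})

test_that("volume is conserved on a dense angle grid", {
  th <- seq(0, 89 * pi / 180, length.out = 1000)
  V0 <- 4 / 3 * pi * 10^3
  V <- vapply(th, function(t) geometry_at_angle(t, 10)$V, numeric(1))
  expect_true(all(abs(V - V0) / V0 < 1e-10))
})

test_that("closed-form reduced volume equals direct evaluation from V and A", {
  th <- seq(0, 89 * pi / 180, length.out = 1000)
  nu_closed <- reduced_volume_of_angle(th)
  nu_direct <- vapply(th, function(t) {
    g <- geometry_at_angle(t, 10)
    6 * sqrt(pi) * g$V / g$A^1.5
  }, numeric(1))
  expect_true(all(abs(nu_closed - nu_direct) < 1e-12))
  expect_equal(reduced_volume_of_angle(0), 1)
  expect_equal(reduced_volume_of_angle(pi / 3), 0.9296, tolerance = 1e-4)
  expect_equal(reduced_volume_of_angle(pi / 2 - 1e-12), 0.7698, tolerance = 1e-4)
  expect_true(all(diff(nu_closed) < 0))  # strictly decreasing
})

test_that("unstretched area expands linearly and rejects non-physical cold", {
  p <- central_params(R0 = 10, T0 = -3)
  expect_equal(unstretched_area(p, -3), 4 * pi * 100)
  expect_equal(unstretched_area(p, 40), 4 * pi * 100 * (1 + 1.3e-3 * 43),
               tolerance = 1e-12)
  expect_equal(unstretched_area(p, 40), 1326.9, tolerance = 1e-4)
  p0 <- central_params(alpha = 1e-8)
  expect_equal(unstretched_area(p0, 40), unstretched_area(p0, 0),
               tolerance = 1e-6)
  expect_error(unstretched_area(central_params(alpha = 0.1), -3000))
})

test_that("reduced volume of temperature brackets 1 at T0", {
  p <- central_params(T0 = -3)
  expect_equal(reduced_volume_of_temperature(p, -3), 1)
  expect_equal(reduced_volume_of_temperature(p, 40), 1.0559^-1.5,
               tolerance = 1e-4)
  expect_equal(reduced_volume_of_temperature(p, -13), 0.987^-1.5,
               tolerance = 1e-4)
  expect_gt(reduced_volume_of_temperature(p, -10), 1)
})

test_that("zero-stretch angle inverts the reduced volume and grows with T", {
  p <- central_params(T0 = -3)
  expect_equal(zero_stretch_angle(p, -3), 0)
  expect_equal(zero_stretch_angle(p, -20), 0)  # turgid sphere below T0
  th40 <- zero_stretch_angle(p, 40)
  expect_equal(th40 * 180 / pi, 62.0, tolerance = 1e-2)
  # nu target 0.9846 -> 38.6 deg
  a <- dnaguv:::.angle_of_reduced_volume(0.9846)
  expect_equal(a * 180 / pi, 38.6, tolerance = 1e-2)
  # mutual inverse property
  for (T_C in c(5, 15, 25, 40)) {
    th <- zero_stretch_angle(p, T_C)
    expect_equal(reduced_volume_of_angle(th),
                 reduced_volume_of_temperature(p, T_C), tolerance = 1e-5)
  }
  Ts <- seq(0, 40, by = 5)
  expect_true(all(diff(zero_stretch_angle(p, Ts)) > 0))
  expect_error(dnaguv:::.angle_of_reduced_volume(0.5), "geometric range")
})

test_that("total area increases and centre distance decreases with angle", {
  th <- seq(1e-3, 89 * pi / 180, length.out = 500)
  g <- dnaguv:::.geometry_grid(th, 10, 14.5)
  expect_true(all(diff(g$A) > 0))
  expect_true(all(diff(g$D) < 0))
})

test_that("effective patch area has the rim limit pi R L and stays positive", {
  # theta -> 0: Ap -> 0 but Ap_eff -> pi R L
  g0 <- geometry_at_angle(1e-9, 10, 14.5)
  expect_equal(g0$Ap_eff, pi * 10 * 14.5e-3, tolerance = 1e-6)
  expect_equal(g0$Ap_eff, 0.4555, tolerance = 1e-3)
  # at 60 deg the rim is a negligible correction: 2 pi r_p s* ~ 0.24 um^2
  g <- geometry_at_angle(pi / 3, 10, 14.5)
  rim <- 2 * pi * (g$R * sin(pi / 3)) * (14.5e-3 / (2 * tan(pi / 3)))
  expect_equal(g$Ap_eff - g$Ap, rim, tolerance = 1e-12)
  expect_equal(rim, 0.24, tolerance = 1e-2)
  expect_lt(rim / g$Ap, 1e-3)
  # L = 0 collapses the rim
  expect_equal(geometry_at_angle(pi / 4, 10, L = 0)$Ap_eff,
               geometry_at_angle(pi / 4, 10, L = 0)$Ap)
  # continuity and positivity over the full angle range
  th <- seq(0, 89 * pi / 180, length.out = 2000)
  eff <- dnaguv:::.geometry_grid(th, 10, 14.5)$Ap_eff
  expect_true(all(eff > 0))
  expect_true(all(abs(diff(eff)) < 0.5))  # no jumps on a fine grid
  g2 <- geometry_at_angle(pi / 3, 10, 14.5)
  expect_equal(effective_patch_area(g2, 14.5), g2$Ap_eff)
})
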