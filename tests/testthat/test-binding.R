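test_that("tether count is fixed at the grafting area", {
  expect_equal(tethers_per_vesicle(390, 10), 390 * 4 * pi * 100)
  expect_equal(tethers_per_vesicle(390, 10), 490088, tolerance = 1e-5)
  expect_equal(tethers_per_vesicle(0, 10), 0)
  expect_equal(log(tethers_per_vesicle(390, 10)), 13.1, tolerance = 1e-2)
})

test_that("rotational cost matches the displacement-averaged rod integrals", {
  L <- 14.5; rho0 <- 0.6
  expect_equal(rotational_entropy_cost(L, rho0), log(4 * pi * rho0 * L^3),
               tolerance = 1e-12)
  expect_equal(rotational_entropy_cost(2 * L, rho0) -
                 rotational_entropy_cost(L, rho0), 3 * log(2),
               tolerance = 1e-12)
  # independent oracle: bound-pair density 1/(2 pi rho0 d_t L^2) integrated
  # over lateral displacement y with weight 2 pi y dy
  loop_int <- stats::integrate(function(y) {
    2 * pi * y * 0.5 / (2 * pi * rho0 * y * L^2)
  }, 0, 2 * L, rel.tol = 1e-12)$value
  bridge_int <- stats::integrate(function(y) {
    2 * pi * y / (2 * pi * rho0 * sqrt(L^2 + y^2) * L^2)
  }, 0, sqrt(3) * L, rel.tol = 1e-12)$value
  expect_equal(loop_int, 1 / (rho0 * L), tolerance = 1e-9)
  expect_equal(bridge_int, loop_int, tolerance = 1e-9)  # loop/bridge equality
  # normalizing by the 4 pi L^2 reference disc gives the Boltzmann weight
  expect_equal(loop_int / (pi * (2 * L)^2),
               exp(-rotational_entropy_cost(L, rho0)), tolerance = 1e-9)
})

test_that("translational cost penalizes small available areas", {
  A <- 4 * pi * 100
  expect_equal(translational_entropy_cost(A, A, 14.5), 13.07, tolerance = 1e-2)
  Ap <- 250
  expect_equal(translational_entropy_cost(Ap, A, 14.5) -
                 translational_entropy_cost(A, A, 14.5), log(A / Ap),
               tolerance = 1e-12)
  expect_error(translational_entropy_cost(0, A, 14.5), "> 0")
})

test_that("bond free energies couple to geometry only via available areas", {
  p <- central_params()
  g <- geometry_at_angle(pi / 3, 10, p$L)
  be <- bond_free_energies(p, g, 60)
  expect_equal(be$dG_loop - be$dG_bridge, log(g$Ap_eff / g$A),
               tolerance = 1e-12)
  expect_gt(be$dS_rot_cost, 0)
  expect_gt(be$dS_trans_loop_cost, 0)
  expect_gt(be$dS_trans_bridge_cost, be$dS_trans_loop_cost)
  # loop energy at 60 degC for a typical unstretched-size vesicle:
  # -6.09 + 10.04 + 13.07 ~ 17.0 kBT
  g0 <- raw_geometry(A = 4 * pi * 100, Ap_eff = 4 * pi * 100)
  be0 <- bond_free_energies(p, g0, 60)
  expect_equal(be0$dG_loop, 17.0, tolerance = 2e-2)
  # bridge trans cost for typical patches is in the quoted 16-20 kBT window
  expect_gt(be$dS_trans_bridge_cost, 13)
  expect_lt(be$dS_trans_bridge_cost, 20)
})

test_that("gap-equation solver satisfies the self-consistency residuals", {
  # q_b = q_l = 1 gives x_b = x_l = 1/4 exactly
  N <- 1000
  f <- solve_bond_fractions(log(N / 2), log(N / 2), N)
  expect_equal(f$q_b, 1); expect_equal(f$q_l, 1)
  expect_equal(f$x_b, 0.25, tolerance = 1e-14)
  expect_equal(f$x_l, 0.25, tolerance = 1e-14)
  # residuals x_i = (1 - x_b - x_l)^2 q_i over random states
  set.seed(42)
  for (k in 1:50) {
    dGb <- runif(1, -10, 25); dGl <- runif(1, -10, 25)
    f <- solve_bond_fractions(dGb, dGl, N)
    x <- f$x_b + f$x_l
    expect_lt(abs(f$x_b - (1 - x)^2 * f$q_b), 1e-12 * max(1, f$x_b))
    expect_lt(abs(f$x_l - (1 - x)^2 * f$q_l), 1e-12 * max(1, f$x_l))
  }
  # melted and saturated limits
  weak <- solve_bond_fractions(40, 40, N)
  q <- weak$q_b + weak$q_l
  expect_equal(weak$x_b + weak$x_l, q - 2 * q^2, tolerance = 1e-8)
  strong <- solve_bond_fractions(-40, -40, N)
  expect_lt(strong$x_b + strong$x_l, 1)
  expect_gt(strong$x_b + strong$x_l, 0.999)
  expect_error(solve_bond_fractions(0, 0, 1), "N must be >= 2")
})

test_that("hybridization free energy is non-positive and decreasing in q", {
  expect_equal(hybridization_free_energy(list(x_b = 0, x_l = 0, N = 10)), 0)
  f <- list(x_b = 0.25, x_l = 0.25, N = 1e5)
  expect_equal(hybridization_free_energy(f),
               2e5 * (log(0.5) + 0.25), tolerance = 1e-12)
  expect_equal(hybridization_free_energy(f), -8.86e4, tolerance = 1e-3)
  # weak-binding limit: ~ -N x (one kBT per bond)
  fw <- list(x_b = 5e-4, x_l = 5e-4, N = 1e5)
  expect_equal(hybridization_free_energy(fw), -1e5 * 1e-3, tolerance = 2e-3)
  # monotone in q
  N <- 1e4
  U <- vapply(seq(-5, 5, by = 0.5), function(lq) {
    f <- solve_bond_fractions(log(N / 2) - lq, Inf, N)
    hybridization_free_energy(f)
  }, numeric(1))
  expect_true(all(diff(U) < 0))
})

test_that("loop/bridge partitioning is set by the relative patch area", {
  set.seed(7)
  for (k in 1:100) {
    p <- central_params(R0 = runif(1, 5, 15), T0 = runif(1, -5, 5))
    th <- runif(1, 1, 85) * pi / 180
    T_C <- runif(1, 0, 60)
    g <- geometry_at_angle(th, p$R0, p$L)
    be <- bond_free_energies(p, g, T_C)
    f <- solve_bond_fractions(be$dG_bridge, be$dG_loop,
                              tethers_per_vesicle(p$rho_dna, p$R0))
    expect_equal(f$x_l / f$x_b, g$A / g$Ap_eff, tolerance = 1e-9)
  }
})

test_that("mean-field fractions converge to exact enumeration as O(1/N)", {
  dG_b <- 1.2; dG_l <- 0.4
  err <- vapply(c(2, 4, 6, 100, 1000), function(N) {
    mf <- solve_bond_fractions(dG_b, dG_l, N)
    ex <- exact_bond_fractions(N / 2, dG_b, dG_l)
    max(abs(mf$x_b - ex$x_b), abs(mf$x_l - ex$x_l))
  }, numeric(1))
  # bounded by ~0.5/N at every size, and decreasing
  expect_true(all(err < 0.5 / c(2, 4, 6, 100, 1000)))
  expect_gt(err[4] / err[5], 5)  # ~10x shrink from N=100 to N=1000
  # free energy agrees to O(1) out of an extensive total
  mf <- solve_bond_fractions(dG_b, dG_l, 1000)
  ex <- exact_bond_fractions(500, dG_b, dG_l)
  expect_lt(abs(hybridization_free_energy(mf) - ex$U_hyb), 2)
})
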