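test_that("g-tensor anisotropy frequencies from the principal values", {
  g <- g_tensor(2.00755, 2.00555, 2.0023)
  ga <- gamma_anisotropies(g, 9.403)
  # printed to the MHz: (-373, 107)
  expect_equal(ga$gamma02 / (2 * pi * 1e6), -373, tolerance = 5e-4)
  expect_equal(ga$gamma22 / (2 * pi * 1e6), 107, tolerance = 5e-3)
  # isotropic tensor: both vanish; axial tensor: gamma22 vanishes
  gi <- gamma_anisotropies(g_tensor(2.005, 2.005, 2.005), 9.4)
  expect_equal(c(gi$gamma02, gi$gamma22), c(0, 0))
  gax <- gamma_anisotropies(g_tensor(2.007, 2.007, 2.002), 9.4)
  expect_equal(gax$gamma22, 0)
  expect_lt(gax$gamma02, 0)
})

test_that("Clebsch-Gordan coefficients: known values, selection rules, unitarity", {
  expect_equal(clebsch_gordan(2, 0, 0, 0, 2, 0), 1, tolerance = 1e-14)
  # <j m j -m | 0 0> = (-1)^(j-m)/sqrt(2j+1)
  expect_equal(clebsch_gordan(2, 0, 2, 0, 0, 0), 1 / sqrt(5), tolerance = 1e-13)
  expect_equal(clebsch_gordan(2, 2, 2, -2, 0, 0), 1 / sqrt(5), tolerance = 1e-13)
  expect_equal(clebsch_gordan(3, 1, 3, -1, 0, 0), 1 / sqrt(7), tolerance = 1e-13)
  # selection rules
  expect_equal(clebsch_gordan(2, 0, 2, 0, 5, 0), 0)   # triangle ok, parity 0
  expect_equal(clebsch_gordan(2, 1, 2, 1, 2, 0), 0)   # M != m1 + m2
  expect_equal(clebsch_gordan(2, 0, 2, 0, 8, 0), 0)   # outside triangle
  # unitarity: sum over J of squares = 1 for fixed (j1 m1 j2 m2)
  for (m1 in 0:2) for (m2 in -2:2) {
    tot <- sum(vapply(abs(m1 + m2):4, function(J)
      clebsch_gordan(2, m1, 2, m2, J, m1 + m2)^2, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  expect_error(clebsch_gordan(2.3, 0, 2, 0, 2, 0), "integers")
})

test_that("basis bookkeeping follows the closed-form count", {
  b2 <- sle_basis(2)
  expect_equal(b2$ntot, 3)
  expect_equal(b2$index, data.frame(L = c(0, 2, 2), M = c(0, 0, 2)))
  expect_equal(sle_basis(0)$ntot, 1)
  for (L in c(2, 8, 12, 16))
    expect_equal(sle_basis(L)$ntot, L^2 / 8 + 3 * L / 4 + 1)
  expect_error(sle_basis(3), "even")
  expect_error(sle_basis(-2), "even")
})

test_that("coupling matrices match the rank-2 selection rules and the
           triple-Wigner quadrature oracle", {
  b2 <- sle_basis(2)
  cm2 <- coupling_matrices(b2)
  # lowest-order entries (00)<-(20) and (20)<-(00)
  expect_equal(cm2$C0[1, 2], 1 / 5, tolerance = 1e-13)
  expect_equal(cm2$C0[2, 1], 1, tolerance = 1e-13)
  # remaining entries of the Lmax = 2 matrices
  expect_equal(cm2$C0, matrix(c(0, 1 / 5, 0,
                                1, 2 / 7, 0,
                                0, 0, -2 / 7), 3, byrow = TRUE),
               tolerance = 1e-13)
  expect_equal(cm2$C2, matrix(c(0, 0, 2 / 5,
                                0, 0, -4 / 7,
                                1, -2 / 7, 0), 3, byrow = TRUE),
               tolerance = 1e-13)

  # triangle rule: all |L - l| = 4 entries vanish
  b8 <- sle_basis(8)
  cm8 <- coupling_matrices(b8)
  far <- abs(outer(b8$index$L, b8$index$L, "-")) >= 4
  expect_true(all(cm8$C0[far] == 0) && all(cm8$C2[far] == 0))
  mfar <- abs(outer(b8$index$M, b8$index$M, "-")) >= 4
  expect_true(all(cm8$C2[mfar] == 0))

  # independent numerical quadrature of the triple-Wigner integral, Lmax = 10
  b10 <- sle_basis(10)
  cm10 <- coupling_matrices(b10)
  qo <- coupling_matrices_quadrature(b10)
  expect_lt(max(abs(cm10$C0 - qo$C0)), 1e-8)
  expect_lt(max(abs(cm10$C2 - qo$C2)), 1e-8)
})

test_that("operator set: diagonal blocks and Lmax = 0 collapse", {
  sp <- spin_epr()
  rot <- rotational_diffusion(tau_rot = 5e-9)
  g <- nitroxide_gammas()
  ops <- sle_operators(sle_basis(2), sp, rot, g$g02, g$g22)
  expect_equal(diag(ops$CD), c(0, 6, 6))
  expect_equal(ops$r2d[2], sp$R2 + 6 * rot$D_rot, tolerance = 1e-12)
  expect_equal(ops$r1d[1], sp$R1, tolerance = 1e-12)
  Dm <- ops$Delta_m(1e9)
  expect_equal(diag(Dm), 1e9 + g$g02 * diag(ops$C0) + g$g22 * diag(ops$C2),
               tolerance = 1e-9)

  ops0 <- sle_operators(sle_basis(0), sp, rot, g$g02, g$g22)
  offs <- mhz(seq(-500, 500, length.out = 200))
  e0 <- epr_slow_tumbling(offs, ops0)
  bl <- bloch_steady_state(offs, sp)
  expect_equal(e0$abs, bl$abs, tolerance = 1e-12)
  expect_equal(e0$dsp, bl$dsp, tolerance = 1e-12)
  expect_equal(e0$s, bl$s, tolerance = 1e-12)
})

test_that("slow-tumbling EPR: reduced route equals the dense solve and the
           saturation-absorption proportionality holds", {
  sp <- spin_epr()
  offs <- mhz(seq(-650, 650, by = 25))
  for (lmax in c(4, 10)) {
    ops <- ops_for(lmax, sp, 5e-9)
    er <- epr_slow_tumbling(offs, ops)
    ef <- epr_slow_tumbling(offs, ops, method = "full")
    expect_lt(max(abs(er$abs - ef$abs)) / max(abs(er$abs)), 1e-9)
    expect_lt(max(abs(er$dsp - ef$dsp)) / max(abs(er$dsp)), 1e-9)
    expect_lt(max(abs(er$s - ef$s)) / max(er$s), 1e-9)
    # s(offset) = -omega1 T1 abs(offset) at every offset and Lmax
    expect_equal(er$s, -sp$omega1 * sp$T1e * er$abs, tolerance = 1e-12)
    expect_true(all(er$s >= 0 & er$s < 1))
  }
})

test_that("derivative spectrum: analytic derivative, dispersion mixing and
           integral property", {
  sp <- spin_epr()
  ops <- ops_for(8, sp, 5e-9)
  offs <- mhz(seq(-550, 550, by = 50))
  # analytic vs central finite differences of the absorption
  h <- 2 * pi * 1e3
  fd <- (epr_slow_tumbling(offs + h, ops)$abs -
           epr_slow_tumbling(offs - h, ops)$abs) / (2 * h)
  an <- epr_derivative_spectrum(offs, ops)
  expect_lt(max(abs(an - fd)) / max(abs(an)), 1e-6)

  # phi = 0 is the pure in-phase derivative; mixing changes the signal
  expect_identical(epr_derivative_spectrum(offs, ops, phi = 0), an)
  mixed <- epr_derivative_spectrum(offs, ops, phi = 0.1)
  expect_gt(max(abs(mixed - an)), 0)

  # Lmax = 0, low power: derivative of a Lorentzian absorption,
  # d abs / d Delta = 2 w1 T2 Delta / (R2 + Delta^2 T2)^2
  spl <- spin_system(9.403, 1e-4, 100e-9, 20e-9)
  ops0 <- sle_operators(sle_basis(0), spl, rotational_diffusion(tau_rot = 1e-9),
                        0, 0)
  d <- mhz(seq(-40, 40, by = 5))
  dan <- epr_derivative_spectrum(d, ops0)
  P0 <- spl$R2 + spl$omega1^2 * spl$T1e + d^2 * spl$T2e
  expect_equal(dan, 2 * spl$omega1 * spl$T2e * d / P0^2, tolerance = 1e-10)

  # wide-grid integral of the in-phase derivative vanishes
  wide <- mhz(seq(-3000, 3000, by = 5))
  ds <- epr_derivative_spectrum(wide, ops)
  integral <- sum(ds) * (wide[2] - wide[1])
  expect_lt(abs(integral) / max(abs(cumsum(ds) * (wide[2] - wide[1]))), 1e-3)
})

test_that("limits: motional narrowing and Lmax convergence at the fitted
           tumbling time", {
  sp <- spin_epr()
  g <- nitroxide_gammas()
  # tau_rot -> 0: unit-peak line shape tends to the 2/T2-wide Lorentzian
  ops <- ops_for(2, sp, 1e-12)
  offs <- mhz(seq(-80, 80, length.out = 161))
  en <- epr_slow_tumbling(offs, ops)$abs
  bl <- bloch_steady_state(offs, sp)$abs
  expect_lt(max(abs(en / max(abs(en)) - bl / max(abs(bl)))), 0.02)

  # Lmax = 8 vs 10 at the fitted tumbling time 5.2 ns: converged below 1 %
  offs2 <- mhz(seq(-700, 700, by = 10))
  a8 <- epr_slow_tumbling(offs2, ops_for(8, sp, 5.2e-9))$abs
  a10 <- epr_slow_tumbling(offs2, ops_for(10, sp, 5.2e-9))$abs
  expect_lt(max(abs(a8 - a10)) / max(abs(a10)), 0.01)
})
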