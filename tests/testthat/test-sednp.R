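test_that("slow-tumbling static-coupling rates: basis collapse and route
           agreement", {
  sp <- spin_dnp()
  offs <- mhz(seq(-600, 600, by = 60))
  d2 <- 3e10
  # Lmax = 0 reduces to the homogeneous-line rates
  ops0 <- ops_for(0, sp, 5e-9)
  p0 <- se_rates_slow_solid(offs, ops0, d2)
  sc <- se_rates_solid_lorentzian(offs, d2, sp)
  expect_lt(max(abs(p0$v_plus - sc$v_plus)) / max(sc$v_plus), 1e-10)
  expect_lt(max(abs(p0$pv_minus - sc$pv_minus)) / max(abs(sc$pv_minus)), 1e-10)

  # reduced route vs dense 3ntot inversion at Lmax = 10
  ops <- ops_for(10, sp, 5e-9)
  rr <- se_rates_slow_solid(offs, ops, d2)
  rf <- se_rates_slow_solid(offs, ops, d2, method = "full")
  expect_lt(max(abs(rr$v_plus - rf$v_plus)) / max(rr$v_plus), 1e-8)
  expect_lt(max(abs(rr$pv_minus - rf$pv_minus)) / max(abs(rr$pv_minus)), 1e-8)

  # R1IA unaffected by the anisotropy: identical at Lmax = 0 and 10 and
  # equal to the scalar closed form
  expect_equal(rr$R1IA[1], p0$R1IA[1], tolerance = 1e-14)
  expect_equal(rr$R1IA[1], d2 * Re(1 / (sp$R1 + 1i * sp$omega_I)),
               tolerance = 1e-14)
})

test_that("slow-tumbling liquid rates: spectral-density collapse and the
           scalar R1IA identity", {
  sp <- spin_dnp()
  offs <- mhz(seq(-500, 500, by = 100))
  # j11 = 1/s reproduces the static-coupling branch
  for (lmax in c(0, 6)) {
    ops <- ops_for(lmax, sp, 5e-9)
    st <- se_rates_slow_solid(offs, ops, 2e10)
    lq <- se_rates_slow_liquid(offs, ops, 2e10, function(s) 1 / s)
    expect_lt(max(abs(st$v_plus - lq$v_plus)) / max(st$v_plus), 1e-9)
    expect_lt(max(abs(st$pv_minus - lq$pv_minus)) / max(abs(st$pv_minus)), 1e-9)
  }
  # Lmax = 0 equals the homogeneous-line liquid rates
  tau <- 6e-9
  j <- function(s) j11_ffhs(s, tau)
  ops0 <- ops_for(0, sp, 5e-9)
  l0 <- se_rates_slow_liquid(offs, ops0, 2e10, j)
  ll <- se_rates_liquid_lorentzian(offs, 2e10, j, sp)
  expect_lt(max(abs(l0$v_plus - ll$v_plus)) / max(ll$v_plus), 1e-9)
  expect_lt(max(abs(l0$pv_minus - ll$pv_minus)) / max(abs(ll$pv_minus)), 1e-9)

  # R1IA from the matrix route equals the scalar spectral-density form
  r1ia_scalar <- 2e10 * Re(j11_ffhs(sp$R1 + 1i * sp$omega_I, tau))
  for (lmax in c(0, 4, 10)) {
    ops <- ops_for(lmax, sp, 5e-9)
    lr <- se_rates_slow_liquid(0, ops, 2e10, j)
    expect_equal(lr$R1IA, r1ia_scalar, tolerance = 1e-12)
  }
})

test_that("rate-profile structure: parity, slow-tumbling asymmetry and the
           solid-case line match", {
  sp <- spin_dnp()
  offs <- mhz(seq(-600, 600, by = 10))
  # Lmax = 0: v+ even, pv- odd
  p0 <- se_rates_slow_solid(offs, ops_for(0, sp, 5e-9), 1)
  expect_lt(max(abs(p0$v_plus - rev(p0$v_plus))) / max(p0$v_plus), 1e-10)
  expect_lt(max(abs(p0$pv_minus + rev(p0$pv_minus))) / max(abs(p0$pv_minus)),
            1e-10)
  expect_true(all(p0$p > 0 & p0$p <= 1))

  # tau_rot = 20 ns: v+ is measurably asymmetric
  p20 <- se_rates_slow_solid(offs, ops_for(10, sp, 20e-9), 1)
  expect_gt(max(abs(p20$v_plus - rev(p20$v_plus))) / max(p20$v_plus), 0.05)

  # static coupling: the SE line of v- matches that of v+ near +omega_I;
  # the FFHS liquid lines differ visibly
  sel <- abs(offs - sp$omega_I) < 2 * pi * 150e6
  ps <- se_rates_slow_solid(offs, ops_for(10, sp, 2e-9), 1)
  expect_lt(abs(max(abs(ps$v_minus[sel])) / max(ps$v_plus[sel]) - 1), 0.01)
  pl <- se_rates_slow_liquid(offs[sel], ops_for(10, sp, 2e-9), 1,
                             function(s) j11_ffhs(s, 6e-9))
  expect_gt(max(abs(pl$v_minus)) / max(pl$v_plus), 1.2)
})

test_that("SE transfer rates are insensitive to T1e while saturation is not", {
  offs <- mhz(seq(-600, 600, by = 20))
  tau <- 6e-9
  j <- function(s) j11_ffhs(s, tau)
  p100 <- se_rates_slow_liquid(offs, ops_for(10, spin_dnp(100e-9), 5e-9), 1, j)
  p500 <- se_rates_slow_liquid(offs, ops_for(10, spin_dnp(500e-9), 5e-9), 1, j)
  expect_lt(max(abs(p100$v_plus - p500$v_plus)) / max(p100$v_plus), 0.01)
  expect_lt(max(abs(p100$v_minus - p500$v_minus)) / max(abs(p100$v_minus)),
            0.01)
  expect_gt(max(abs(p100$s - p500$s)) / max(p100$s), 0.2)
  # v+ per unit coupling stays on the ~1 ps scale, so v+ T1I << 1 for
  # millisecond nuclear T1 at the measured coupling strength
  d2T1 <- 2.29  # <delta^2> T1I in 1/ns
  expect_lt(max(p100$v_plus) * d2T1 * 1e-3, 0.01)
})

test_that("mixed DNP spectrum model: signs, components and degenerate cases", {
  sp <- spin_dnp(123e-9)
  ops <- ops_for(6, sp, 5.2e-9)
  offs <- mhz(seq(-700, 700, by = 20))
  tau <- 6.4e-9
  j <- function(s) j11_ffhs(s, tau)
  prof <- dnp_spectrum_model(offs, ops, sigma_OE = 2.43, sigma_SE = 1.51e12,
                             j11 = j)
  # negative OE dip near zero offset, positive SE peak near +omega_I
  i0 <- which.min(abs(offs))
  expect_lt(prof$enhancement[i0], 0)
  ise <- which.min(abs(offs - sp$omega_I))
  expect_gt(prof$enhancement[ise], 0)
  expect_true(all(prof$oe <= 0))
  expect_equal(prof$enhancement, prof$oe + prof$se, tolerance = 1e-14)

  # zero amplitudes give zero; pure OE is proportional to the saturation
  z <- dnp_spectrum_model(offs, ops, 0, 0, j11 = j)
  expect_true(all(z$enhancement == 0))
  oe_only <- dnp_spectrum_model(offs, ops, 2.43, 0, j11 = j)
  sat <- epr_slow_tumbling(offs, ops)$s
  expect_equal(oe_only$enhancement, -2.43 * sat, tolerance = 1e-9)

  # horizontal shift moves the profile
  sh <- dnp_spectrum_model(offs, ops, 2.43, 1.51e12, j11 = j,
                           shift = mhz(50))
  expect_gt(max(abs(sh$enhancement - prof$enhancement)), 0.1)
})
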