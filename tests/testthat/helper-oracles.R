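# Shared fixtures and independent oracles for the test suite.

# Canonical nitroxide-at-9.4-T study conditions (Fig.-style parameters):
# g anisotropies (-373, +107) MHz, T2e = 20 ns; low power 0.02 G for cw-EPR,
# high power 5.5 G for DNP.
nitroxide_gammas <- function() list(g02 = -2 * pi * 373e6, g22 = 2 * pi * 107e6)

spin_epr <- function(T1e = 100e-9) spin_system(9.403, 0.02, T1e, 20e-9)
spin_dnp <- function(T1e = 100e-9) spin_system(9.403, 5.5, T1e, 20e-9)

ops_for <- function(lmax, spin, tau_rot,
                    g = nitroxide_gammas()) {
  sle_operators(sle_basis(lmax), spin,
                rotational_diffusion(tau_rot = tau_rot), g$g02, g$g22)
}

mhz <- function(x) 2 * pi * 1e6 * x

# Frobenius norm that keeps complex magnitudes
fnorm <- function(x) sqrt(sum(Mod(x)^2))

# Independent Wigner small-d element d^j_{m,0}(beta) by the explicit
# combinatorial sum (not via Clebsch-Gordan), used as quadrature oracle.
wigner_d0 <- function(j, m, beta) {
  k <- max(0, -m):min(j, j - m)
  vapply(beta, function(b) {
    sum((-1)^k * sqrt(factorial(j + m) * factorial(j - m)) * factorial(j) /
          (factorial(j - k) * factorial(k) * factorial(j - m - k) *
             factorial(m + k)) *
          cos(b / 2)^(2 * j - m - 2 * k) * sin(b / 2)^(m + 2 * k))
  }, numeric(1))
}

# (2L+1)/(8 pi^2) * int D^L_{M0}* D^2_{K0} D^l_{m0} dOmega reduced to a
# beta quadrature (the alpha integral enforces M = K + m, gamma is trivial).
triple_wigner <- local({
  gq <- NULL
  function(L, M, K, l, m) {
    if (M != K + m) return(0)
    if (is.null(gq)) gq <<- pracma::gaussLegendre(200, 0, pi)
    f <- wigner_d0(L, M, gq$x) * wigner_d0(2, K, gq$x) *
      wigner_d0(l, m, gq$x) * sin(gq$x)
    (2 * L + 1) / 2 * sum(gq$w * f)
  }
})

# Coupling matrices rebuilt from the quadrature oracle, including the
# factor-2 symmetrization exception on M = 0 rows.
coupling_matrices_quadrature <- function(basis) {
  idx <- basis$index
  n <- basis$ntot
  C0 <- matrix(0, n, n)
  C2 <- matrix(0, n, n)
  for (r in seq_len(n)) {
    for (cc in seq_len(n)) {
      L <- idx$L[r]; M <- idx$M[r]; l <- idx$L[cc]; m <- idx$M[cc]
      if (m == M) C0[r, cc] <- triple_wigner(L, M, 0, l, m)
      v <- triple_wigner(L, M, -2, l, m) + triple_wigner(L, M, 2, l, m)
      if (M == 0) v <- 2 * triple_wigner(L, 0, -2, l, m)
      C2[r, cc] <- v
    }
  }
  list(C0 = C0, C2 = C2)
}

# Synthetic spectra used by the recovery studies (same forward model and
# truncation as the fits; Table-1-style ground truth).
epr_truth <- list(gamma02 = -373, gamma22 = 107, tau_rot = 5.2, phi = -1.3)
dnp_truth <- list(tau_ffhs = 6.4, T1e = 123, sigma_OE = 2.43, sigma_SE = 1.51)

make_epr_synthetic <- function(lmax = 6, grid = seq(-700, 700, by = 10),
                               truth = epr_truth, amplitude = 1) {
  ops <- ops_for(lmax, spin_epr(), truth$tau_rot * 1e-9,
                 list(g02 = mhz(truth$gamma02), g22 = mhz(truth$gamma22)))
  y <- epr_derivative_spectrum(mhz(grid), ops, phi = truth$phi * pi / 180)
  data.frame(axis = grid, value = amplitude * y)
}

make_dnp_synthetic <- function(lmax = 6, grid = seq(-700, 700, by = 12.5),
                               truth = dnp_truth, tau_rot = 5.2) {
  ops <- ops_for(lmax, spin_dnp(truth$T1e * 1e-9), tau_rot * 1e-9)
  tau <- truth$tau_ffhs * 1e-9
  prof <- dnp_spectrum_model(mhz(grid), ops, truth$sigma_OE,
                             truth$sigma_SE * 1e12,
                             j11 = function(s) j11_ffhs(s, tau))
  data.frame(axis = grid, value = prof$enhancement)
}
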