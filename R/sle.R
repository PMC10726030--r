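#' Secular g-tensor anisotropy frequencies
#'
#' Converts the principal g values into the two angular frequencies that
#' scale the rank-2 orientation dependence of the electronic Larmor
#' frequency:
#' \deqn{\gamma_0^2 = \tfrac{2}{3}\left[g_{zz} - \tfrac{1}{2}(g_{xx}+g_{yy})\right]
#'   \mu_B B_0/\hbar, \qquad
#'   \gamma_2^2 = \tfrac{1}{\sqrt 6}(g_{xx} - g_{yy})\,\mu_B B_0/\hbar.}
#' For a typical nitroxide tensor diag(2.00755, 2.00555, 2.0023) at 9.403 T
#' these are about -373 and +107 MHz (ordinary frequency).
#'
#' @param g a [g_tensor()].
#' @param B0 static field (T), > 0.
#' @return list with \code{gamma02} and \code{gamma22} (rad/s).
#' @export
gamma_anisotropies <- function(g, B0) {
  .stopifnot_finite(B0 = B0)
  if (B0 <= 0) stop("B0 must be > 0", call. = FALSE)
  wB <- .const$mu_B * B0 / .const$hbar
  list(gamma02 = (2 / 3) * (g$gzz - (g$gxx + g$gyy) / 2) * wB,
       gamma22 = (1 / sqrt(6)) * (g$gxx - g$gyy) * wB)
}

#' Symmetrized Wigner-expansion basis for isotropic tumbling
#'
#' Index set of the orientational expansion coefficients that couple to the
#' observable: pairs (L, M) with L even, 0 <= L <= Lmax, M even,
#' 0 <= M <= L, ordered by (L, M). The count is
#' \eqn{n_{tot} = L_{max}^2/8 + 3 L_{max}/4 + 1}; the first entry (0, 0)
#' carries the orientational average that is detected.
#'
#' @param Lmax even truncation order, >= 0.
#' @return list of class \code{"sle_basis"}: \code{Lmax}, \code{index}
#'   (data frame with columns L, M) and \code{ntot}.
#' @examples
#' sle_basis(2)$ntot   # 3
#' sle_basis(8)$ntot   # 15
#' @export
sle_basis <- function(Lmax) {
  if (!is.numeric(Lmax) || length(Lmax) != 1 || !is.finite(Lmax) ||
      Lmax < 0 || Lmax != round(Lmax) || Lmax %% 2 != 0)
    stop("invalid argument: Lmax must be a nonnegative even integer", call. = FALSE)
  L <- unlist(lapply(seq(0, Lmax, by = 2), function(l) rep(l, l / 2 + 1)))
  M <- unlist(lapply(seq(0, Lmax, by = 2), function(l) seq(0, l, by = 2)))
  structure(list(Lmax = Lmax,
                 index = data.frame(L = L, M = M),
                 ntot = length(L)),
            class = "sle_basis")
}

#' Rank-2 coupling matrices of the orientational expansion
#'
#' The offset matrix mixes expansion coefficients through two real
#' ntot x ntot matrices built from Clebsch-Gordan coefficients:
#' \deqn{[C_0]_{LM,\ell m} = \langle 2\,0\,\ell\,m|L\,M\rangle
#'   \langle 2\,0\,\ell\,0|L\,0\rangle}
#' (nonzero only for m = M), and
#' \deqn{[C_2]_{LM,\ell m} = \big(\langle 2,-2,\ell,m|L,M\rangle +
#'   \langle 2,2,\ell,m|L,M\rangle\big)\langle 2\,0\,\ell\,0|L\,0\rangle,}
#' where rows with M = 0 acquire a factor 2 on the surviving
#' \eqn{\langle 2,-2,\ell,2|L,0\rangle} term: in the symmetrized basis the
#' M = 0 coefficients are not averaged over a +/-M pair, so both mirror
#' contributions fall on the same entry. Entries vanish unless
#' |L - l| is 0 or 2 and |M - m| is 0 or 2 (rank-2 triangle rules).
#'
#' @param basis an [sle_basis()].
#' @return list with real matrices \code{C0} and \code{C2}.
#' @export
coupling_matrices <- function(basis) {
  stopifnot(inherits(basis, "sle_basis"))
  idx <- basis$index
  n <- basis$ntot
  C0 <- matrix(0, n, n)
  C2 <- matrix(0, n, n)
  for (r in seq_len(n)) {
    L <- idx$L[r]; M <- idx$M[r]
    for (cc in seq_len(n)) {
      l <- idx$L[cc]; m <- idx$M[cc]
      if (abs(L - l) > 2) next
      cl <- clebsch_gordan(2, 0, l, 0, L, 0)
      if (cl == 0) next
      if (m == M)
        C0[r, cc] <- clebsch_gordan(2, 0, l, m, L, M) * cl
      cg2 <- clebsch_gordan(2, -2, l, m, L, M) +
             clebsch_gordan(2, 2, l, m, L, M)
      if (M == 0) cg2 <- 2 * clebsch_gordan(2, -2, l, m, L, 0)
      C2[r, cc] <- cg2 * cl
    }
  }
  list(C0 = C0, C2 = C2)
}

#' Assemble the expanded Bloch operators for slow tumbling
#'
#' Builds the ntot x ntot operator blocks of the stochastic Liouville
#' dynamics: the diagonal relaxation matrices
#' \eqn{R_{1,2} = R_{1,2} E + D_{rot} C_D} (with \eqn{[C_D] = L(L+1)}), and
#' the offset matrix \eqn{\Delta(\Delta) = \Delta E + \gamma_0^2 C_0 +
#' \gamma_2^2 C_2}, the only block that mixes different (L, M).
#' At Lmax = 0 everything is 1x1 and the machinery reduces to the scalar
#' Bloch quantities.
#'
#' @param basis an [sle_basis()].
#' @param spin a [spin_system()].
#' @param rot a [rotational_diffusion()].
#' @param gamma02,gamma22 anisotropy frequencies (rad/s); see
#'   [gamma_anisotropies()].
#' @return list of class \code{"sle_operators"} with the basis, the spin and
#'   rotation parameters, matrices \code{CD}, \code{C0}, \code{C2},
#'   diagonal vectors \code{r1d}, \code{r2d} (entries of R1, R2), and
#'   \code{Delta_m(offset)}, a function returning the offset matrix.
#' @export
sle_operators <- function(basis, spin, rot, gamma02, gamma22) {
  stopifnot(inherits(basis, "sle_basis"), inherits(spin, "spin_system"),
            inherits(rot, "rotational_diffusion"))
  .stopifnot_finite(gamma02 = gamma02, gamma22 = gamma22)
  cm <- coupling_matrices(basis)
  cd <- basis$index$L * (basis$index$L + 1)
  Gm <- gamma02 * cm$C0 + gamma22 * cm$C2
  structure(list(
    basis = basis, spin = spin, rot = rot,
    gamma02 = gamma02, gamma22 = gamma22,
    CD = diag(cd, basis$ntot), C0 = cm$C0, C2 = cm$C2,
    r1d = spin$R1 + rot$D_rot * cd,
    r2d = spin$R2 + rot$D_rot * cd,
    Gm = Gm,
    Delta_m = function(offset) {
      D <- Gm
      diag(D) <- diag(D) + offset
      D
    }
  ), class = "sle_operators")
}

# Reduced saturation matrix P(Delta) = (R2 + i wI) + w1^2 (R1 + i wI)^-1
#  + Dm (R2 + i wI)^-1 Dm ; omega_I = 0 gives the real matrix P0.
.sle_P <- function(ops, offset, omega_I = 0) {
  Dm <- ops$Delta_m(offset)
  w1 <- ops$spin$omega1
  r1 <- ops$r1d + 1i * omega_I
  r2 <- ops$r2d + 1i * omega_I
  P <- Dm %*% ((1 / r2) * Dm)
  diag(P) <- diag(P) + r2 + w1^2 / r1
  if (omega_I == 0) P <- Re(P)
  P
}

# Full 3ntot x 3ntot expanded Bloch matrix, blocks ordered (x, y, z).
.sle_B_full <- function(ops, offset, omega_I = 0) {
  n <- ops$basis$ntot
  w1 <- ops$spin$omega1
  Dm <- ops$Delta_m(offset)
  Z <- matrix(0, n, n)
  R2m <- diag(ops$r2d, n)
  R1m <- diag(ops$r1d, n)
  B <- rbind(cbind(R2m, Dm, Z),
             cbind(-Dm, R2m, w1 * diag(n)),
             cbind(Z, -w1 * diag(n), R1m))
  if (omega_I != 0) B <- B + 1i * omega_I * diag(3 * n)
  B
}

#' Slow-tumbling cw-EPR spectrum and saturation profile
#'
#' For each offset the reduced route inverts the ntot x ntot matrix
#' \eqn{P_0 = R_2 + \omega_1^2 R_1^{-1} + \Delta R_2^{-1} \Delta} and reads
#' the detected (0,0) component:
#' \eqn{abs = -\omega_1 [P_0^{-1}]_{11}},
#' \eqn{dsp = \omega_1 T_2 [\Delta P_0^{-1}]_{11}},
#' \eqn{s = \omega_1^2 T_1 [P_0^{-1}]_{11}}. The proportionality
#' \eqn{s = -\omega_1 T_1\, abs} survives the g anisotropy at every power.
#' \code{method = "full"} instead solves the full 3ntot x 3ntot steady
#' state, as a cross-check.
#'
#' @param offsets offsets from the isotropic-g resonance (rad/s).
#' @param ops an [sle_operators()].
#' @param method "reduced" (default) or "full".
#' @return data frame with columns \code{offset}, \code{abs}, \code{dsp},
#'   \code{s}.
#' @export
epr_slow_tumbling <- function(offsets, ops, method = c("reduced", "full")) {
  method <- match.arg(method)
  .stopifnot_finite(offsets = offsets)
  n <- ops$basis$ntot
  w1 <- ops$spin$omega1
  T1 <- ops$spin$T1e
  T2 <- ops$spin$T2e
  e1 <- c(1, numeric(n - 1))
  out <- vapply(offsets, function(d) {
    if (method == "reduced") {
      P0 <- .sle_P(ops, d, 0)
      x <- tryCatch(solve(P0, e1),
                    error = function(e) stop("singular P0 at offset ", d,
                                             " rad/s", call. = FALSE))
      absv <- -w1 * x[1]
      dspv <- w1 * T2 * (ops$Delta_m(d) %*% x)[1]
      c(absv, dspv, w1^2 * T1 * x[1])
    } else {
      B <- .sle_B_full(ops, d, 0)
      rhs <- c(numeric(2 * n), ops$spin$R1 * e1)
      sol <- solve(B, rhs)   # components relative to szeq
      absv <- sol[n + 1]
      dspv <- sol[1]
      c(absv, dspv, 1 - sol[2 * n + 1])
    }
  }, numeric(3))
  data.frame(offset = offsets, abs = out[1, ], dsp = out[2, ], s = out[3, ])
}

#' Derivative-mode cw-EPR spectrum with dispersion admixture
#'
#' Analytic derivative of the slow-tumbling spectrum with respect to the
#' scalar offset, using
#' \eqn{\partial P_0/\partial\Delta = R_2^{-1}\Delta + \Delta R_2^{-1}}
#' (no finite differencing). The returned signal is
#' \eqn{(\partial s_y^{00}/\partial\Delta)\cos\phi +
#'      (\partial s_x^{00}/\partial\Delta)\sin\phi}: the mixing angle
#' \eqn{\phi} admixes the out-of-phase (dispersive) derivative, as needed
#' when an experimental spectrum is not purely in-phase.
#'
#' @param offsets offsets (rad/s).
#' @param ops an [sle_operators()].
#' @param phi mixing angle (rad); 0 gives the pure in-phase derivative.
#' @return numeric vector of derivative signal values (per rad/s).
#' @export
epr_derivative_spectrum <- function(offsets, ops, phi = 0) {
  .stopifnot_finite(offsets = offsets, phi = phi)
  n <- ops$basis$ntot
  w1 <- ops$spin$omega1
  e1 <- c(1, numeric(n - 1))
  r2inv <- 1 / ops$r2d
  vapply(offsets, function(d) {
    Dm <- ops$Delta_m(d)
    P0 <- .sle_P(ops, d, 0)
    x <- tryCatch(solve(P0, e1),
                  error = function(e) stop("singular P0 at offset ", d,
                                           " rad/s", call. = FALSE))
    sy <- -w1 * x                               # sy vector / szeq
    dP0 <- r2inv * Dm + Dm %*% diag(r2inv, n)   # R2^-1 Dm + Dm R2^-1
    dsy <- w1 * solve(P0, dP0 %*% x)            # d sy / d Delta
    dsx <- -r2inv * (sy + Dm %*% dsy)
    dsy[1] * cos(phi) + dsx[1] * sin(phi)
  }, numeric(1))
}
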