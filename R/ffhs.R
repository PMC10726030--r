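#' Electron-nucleus dipolar constant
#'
#' \eqn{D_{dip} = (\mu_0/4\pi)\hbar|\gamma_S||\gamma_I|} expressed in
#' rad/s nm^3 (inter-spin distances in this package are in nm). For the
#' free electron and the proton, \eqn{D_{dip}/2\pi \approx 79} kHz nm^3.
#'
#' @param gamma_S,gamma_I gyromagnetic ratios (rad/s/T); defaults are the
#'   free electron and the proton.
#' @return dipolar constant (rad/s nm^3).
#' @examples
#' dipolar_constant() / (2 * pi)  # ~ 7.9e4 kHz nm^3 scale
#' @export
dipolar_constant <- function(gamma_S = .const$gamma_e,
                             gamma_I = .const$gamma_H) {
  .stopifnot_finite(gamma_S = gamma_S, gamma_I = gamma_I)
  if (gamma_S == 0) stop("gamma_S must be nonzero", call. = FALSE)
  .const$mu0_over_4pi * .const$hbar * abs(gamma_S) * abs(gamma_I) * 1e27
}

#' Reduced spectral density of force-free hard-sphere translational diffusion
#'
#' \deqn{j_{11}(s) = \tau \frac{(s\tau)^{1/2} + 4}
#'   {(s\tau)^{3/2} + 4 s\tau + 9 (s\tau)^{1/2} + 9}}
#' with the principal branch of the square root. The diffusive timescale is
#' \eqn{\tau = b^2/D_{trans}}. The full spectral density is
#' \eqn{J_{11}(s) = \langle\delta^2\rangle\, j_{11}(s)}; the reduced form has
#' units of time and carries the entire line-shape information, with all
#' concentration and distance dependence confined to the scale
#' \eqn{\langle\delta^2\rangle}.
#'
#' @param s complex rate argument(s) (rad/s); the real part must be >= 0
#'   (relaxation rates of decaying modes).
#' @param tau diffusive timescale (s), > 0.
#' @param tol tolerance on negative real parts before erroring.
#' @return complex vector, units of time. \code{j11_ffhs(0, tau)} equals
#'   \code{4 * tau / 9}.
#' @examples
#' j11_ffhs(0, 1e-9)            # zero-frequency limit 4 tau / 9
#' Re(j11_ffhs(1i * 2 * pi * 400e6, 6e-9))
#' @export
j11_ffhs <- function(s, tau, tol = 1e-6) {
  if (!is.numeric(tau) || !is.finite(tau) || tau <= 0)
    stop("tau must be a positive finite number", call. = FALSE)
  s <- as.complex(s)
  if (any(!is.finite(s))) stop("non-finite spectral-density argument", call. = FALSE)
  if (any(Re(s) < -tol * (abs(s) + 1 / tau)))
    stop("invalid argument: j11 requires Re(s) >= 0", call. = FALSE)
  st <- s * tau
  u <- sqrt(st)  # principal branch; Re(st) >= 0 so no cut is crossed
  tau * (u + 4) / (u^3 + 4 * st + 9 * u + 9)
}

#' Volume-averaged squared dipolar coupling
#'
#' \deqn{\langle\delta^2\rangle = D_{dip}^2 \frac{6\pi}{5} \frac{N}{3 b^3}}
#' the average of the single-pair coupling strength over the sample volume
#' times the electron number density N.
#'
#' @param b contact distance (nm), > 0.
#' @param N electron number density (nm^-3), >= 0.
#' @param D_dip dipolar constant (rad/s nm^3); see [dipolar_constant()].
#' @return \eqn{\langle\delta^2\rangle} in (rad/s)^2.
#' @examples
#' avg_delta2(b = 0.61, N = 1 / 26)  # ~ 5.2e10 s^-2
#' @export
avg_delta2 <- function(b, N, D_dip = dipolar_constant()) {
  .stopifnot_finite(b = b, N = N, D_dip = D_dip)
  if (b <= 0) stop("invalid parameter: b must be > 0", call. = FALSE)
  if (N < 0) stop("invalid parameter: N must be >= 0", call. = FALSE)
  D_dip^2 * (6 * pi / 5) * N / (3 * b^3)
}

#' FFHS model parameters
#'
#' Convenience bundle tying the contact distance, diffusion coefficient,
#' diffusive timescale and dipolar scale together, with unit conversions
#' (b in nm, D in nm^2/us, tau in s).
#'
#' @param b contact distance (nm).
#' @param D_trans relative translational diffusion coefficient (nm^2/us);
#'   give either this or \code{tau}.
#' @param tau diffusive timescale (s).
#' @param N electron number density (nm^-3).
#' @param D_dip dipolar constant (rad/s nm^3).
#' @return list of class \code{"ffhs_params"} with fields \code{b},
#'   \code{D_trans}, \code{tau}, \code{N}, \code{D_dip}, \code{avg_delta2}.
#' @export
ffhs_params <- function(b, D_trans = NULL, tau = NULL, N,
                        D_dip = dipolar_constant()) {
  if (is.null(D_trans) == is.null(tau))
    stop("give exactly one of D_trans or tau", call. = FALSE)
  .stopifnot_finite(b = b, N = N)
  if (b <= 0) stop("b must be > 0", call. = FALSE)
  if (is.null(tau)) {
    if (D_trans <= 0) stop("D_trans must be > 0", call. = FALSE)
    tau <- b^2 / D_trans * 1e-6            # nm^2 / (nm^2/us) -> s
  } else {
    if (tau <= 0) stop("tau must be > 0", call. = FALSE)
    D_trans <- b^2 / tau * 1e-6            # nm^2/s -> nm^2/us
  }
  structure(list(b = b, D_trans = D_trans, tau = tau, N = N, D_dip = D_dip,
                 avg_delta2 = avg_delta2(b, N, D_dip)),
            class = "ffhs_params")
}

#' Evaluate a scalar spectral density at a square complex matrix argument
#'
#' Computes \eqn{Q = U\,\mathrm{diag}(j_{11}(\lambda_n))\,U^{-1}} from the
#' eigendecomposition \eqn{B U = U \Lambda}. The eigenvalues of a physical
#' relaxation matrix have nonnegative real parts; a large negative real part
#' signals unstable dynamics and raises an error, as does a near-defective
#' eigenvector matrix.
#'
#' @param j11 scalar function of a complex argument (vectorized).
#' @param B square complex matrix.
#' @param cond_tol maximum allowed condition number of the eigenvector
#'   matrix before the decomposition is declared degenerate.
#' @param stab_tol tolerance on negative eigenvalue real parts, relative to
#'   the matrix scale.
#' @return complex matrix Q of the same dimension; Q commutes with B.
#' @examples
#' B <- diag(c(1 + 2i, 3, 5))
#' matrix_spectral_density(function(s) 1 / s, B)  # equals solve(B)
#' @export
matrix_spectral_density <- function(j11, B, cond_tol = 1e8, stab_tol = 1e-9) {
  if (!is.matrix(B) || nrow(B) != ncol(B))
    stop("B must be a square matrix", call. = FALSE)
  e <- eigen(B)
  U <- e$vectors
  rc <- rcond(U)
  if (!is.finite(rc) || rc < 1 / cond_tol)
    stop("numerical degeneracy: eigenvector condition number exceeds ",
         format(cond_tol), call. = FALSE)
  scale <- max(abs(e$values))
  if (any(Re(e$values) < -stab_tol * scale))
    stop("unstable dynamics: eigenvalue with negative real part", call. = FALSE)
  lam <- e$values
  lam[Re(lam) < 0] <- 1i * Im(lam[Re(lam) < 0])  # clip roundoff-negative parts
  U %*% (j11(lam) * solve(U))
}
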