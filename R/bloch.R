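#' Bloch matrix of the electronic spin, optionally shifted by the nuclear
#' Larmor frequency
#'
#' The 3x3 matrix that generates the rotating-frame dynamics of
#' (sx, sy, sz). Adding \code{1i * omega_I} on the diagonal produces the
#' matrix that governs the electron-nucleus coherences driven in the solid
#' effect.
#'
#' @param offset frequency offset from the electronic resonance (rad/s).
#' @param spin a [spin_system()].
#' @param omega_I diagonal shift (rad/s); 0 gives the classical Bloch matrix.
#' @param omega1 optional override of the nutation frequency (rad/s).
#' @return complex 3x3 matrix.
#' @keywords internal
bloch_matrix <- function(offset, spin, omega_I = 0, omega1 = spin$omega1) {
  matrix(c(spin$R2 + 1i * omega_I, offset,                0,
           -offset,                spin$R2 + 1i * omega_I, omega1,
           0,                      -omega1,               spin$R1 + 1i * omega_I),
         nrow = 3, byrow = TRUE)
}

#' Steady state of the Bloch equations for a homogeneous line
#'
#' Solves the steady-state Bloch equations in closed form. All magnetizations
#' are reported relative to the thermal value szeq, which is never
#' materialized. The absorptive line shape is \eqn{abs = -\omega_1 / P_0}
#' with \eqn{P_0 = R_2 + \omega_1^2 T_1 + \Delta^2 T_2}, the dispersive one is
#' \eqn{dsp = -\Delta T_2\, abs}, and the saturation factor is
#' \eqn{s = -\omega_1 T_1\, abs}, exactly proportional to the absorption at
#' every microwave power.
#'
#' @param offset frequency offset(s) from resonance (rad/s); vectorized.
#' @param spin a [spin_system()].
#' @return A data frame with columns \code{offset}, \code{sx}, \code{sy},
#'   \code{sz} (relative to szeq), \code{abs}, \code{dsp} and \code{s}.
#' @examples
#' sp <- spin_system(9.403, 5.5, 100e-9, 20e-9)
#' bloch_steady_state(0, sp)$s  # on-resonance saturation
#' @export
bloch_steady_state <- function(offset, spin) {
  .stopifnot_finite(offset = offset)
  w1 <- spin$omega1
  P0 <- spin$R2 + w1^2 * spin$T1e + offset^2 * spin$T2e
  abs_ <- -w1 / P0
  dsp <- -offset * spin$T2e * abs_
  s <- -w1 * spin$T1e * abs_
  data.frame(offset = offset, sx = dsp, sy = abs_, sz = 1 - s,
             abs = abs_, dsp = dsp, s = s)
}

#' Solid-effect rate constants for a static dipolar coupling and a
#' homogeneous EPR line
#'
#' Computes the thermal coherence relaxation rate \code{R1IA}, the
#' microwave-driven nuclear relaxation rate \code{v_plus} and the
#' polarization-transfer rate \code{pv_minus} for an electron-nucleus pair
#' with fixed dipolar strength \code{delta2}. The default route uses the
#' closed-form expressions; \code{method = "matrix"} inverts the 3x3
#' coherence matrix numerically instead, and the two agree to rounding.
#'
#' @param offset offset(s) from the electronic resonance (rad/s).
#' @param delta2 squared dipolar coupling strength ((rad/s)^2), >= 0.
#' @param spin a [spin_system()]; its \code{omega_I} must be > 0.
#' @param method "closed" (default) or "matrix".
#' @return Data frame with columns \code{offset}, \code{v_plus},
#'   \code{pv_minus}, \code{R1IA} (all 1/s).
#' @examples
#' sp <- spin_system(9.403, 5.5, 100e-9, 20e-9)
#' se_rates_solid_lorentzian(2 * pi * 400e6, 1e10, sp)
#' @export
se_rates_solid_lorentzian <- function(offset, delta2, spin,
                                      method = c("closed", "matrix")) {
  method <- match.arg(method)
  .stopifnot_finite(offset = offset, delta2 = delta2)
  if (delta2 < 0) stop("invalid parameter: delta2 must be >= 0", call. = FALSE)
  if (spin$omega_I <= 0)
    stop("invalid parameter: omega_I must be > 0 (finite nuclear Zeeman splitting)",
         call. = FALSE)
  w1 <- spin$omega1
  wI <- spin$omega_I
  r1I <- spin$R1 + 1i * wI
  r2I <- spin$R2 + 1i * wI
  R1IA <- delta2 * Re(1 / r1I)
  if (method == "closed") {
    P0 <- spin$R2 + w1^2 * spin$T1e + offset^2 * spin$T2e
    P <- r2I + w1^2 / r1I + offset^2 / r2I
    v_plus <- -delta2 * w1^2 * Re(1 / (r1I^2 * P))
    pv_minus <- -delta2 * w1^2 * offset / P0 *
      Im((1 / spin$R2 + 1 / r2I) / (r1I * P))
  } else {
    n <- length(offset)
    v_plus <- numeric(n)
    pv_minus <- numeric(n)
    for (k in seq_len(n)) {
      B <- bloch_matrix(offset[k], spin, omega_I = wI)
      Binv <- solve(B)
      P0 <- spin$R2 + w1^2 * spin$T1e + offset[k]^2 * spin$T2e
      v_plus[k] <- delta2 * Re(Binv[3, 3]) - R1IA
      pv_minus[k] <- -delta2 * w1 / P0 *
        Im(Binv[3, 1] + offset[k] * spin$T2e * Binv[3, 2])
    }
  }
  data.frame(offset = offset, v_plus = v_plus, pv_minus = pv_minus,
             R1IA = R1IA)
}

#' Solid-effect rate constants for a translationally modulated dipolar
#' coupling and a homogeneous EPR line
#'
#' The static-coupling rates are generalized to liquids by replacing the
#' inverse of the 3x3 coherence matrix B with the matrix spectral density
#' \eqn{Q = j_{11}(B)}, evaluated by eigendecomposition, and the fixed
#' coupling \code{delta2} with the volume-averaged \code{avg_delta2}.
#' With \code{j11 = function(s) 1/s} this reproduces the static case exactly.
#'
#' @param offset offset(s) from the electronic resonance (rad/s).
#' @param avg_delta2 averaged squared dipolar strength ((rad/s)^2).
#' @param j11 reduced spectral density: a function of a complex rate
#'   argument (rad/s) returning units of time, e.g. built from [j11_ffhs()].
#' @param spin a [spin_system()], \code{omega_I > 0}.
#' @return Data frame with columns \code{offset}, \code{v_plus},
#'   \code{pv_minus}, \code{R1IA} (1/s). \code{R1IA} equals the scalar form
#'   \code{avg_delta2 * Re(j11(R1 + 1i * omega_I))}.
#' @examples
#' sp <- spin_system(9.403, 5.5, 100e-9, 20e-9)
#' j11 <- function(s) j11_ffhs(s, tau = 6e-9)
#' se_rates_liquid_lorentzian(2 * pi * 400e6, 5e10, j11, sp)
#' @export
se_rates_liquid_lorentzian <- function(offset, avg_delta2, j11, spin) {
  .stopifnot_finite(offset = offset, avg_delta2 = avg_delta2)
  if (spin$omega_I <= 0)
    stop("invalid parameter: omega_I must be > 0", call. = FALSE)
  w1 <- spin$omega1
  wI <- spin$omega_I
  R1IA <- avg_delta2 * Re(j11(spin$R1 + 1i * wI))
  n <- length(offset)
  v_plus <- numeric(n)
  pv_minus <- numeric(n)
  for (k in seq_len(n)) {
    B <- bloch_matrix(offset[k], spin, omega_I = wI)
    Q <- matrix_spectral_density(j11, B)
    P0 <- spin$R2 + w1^2 * spin$T1e + offset[k]^2 * spin$T2e
    v_plus[k] <- avg_delta2 * Re(Q[3, 3]) - R1IA
    pv_minus[k] <- -avg_delta2 * w1 / P0 *
      Im(Q[3, 1] + offset[k] * spin$T2e * Q[3, 2])
  }
  data.frame(offset = offset, v_plus = v_plus, pv_minus = pv_minus,
             R1IA = R1IA)
}

#' Solid-effect enhancement from the rate constants
#'
#' Evaluates both the exact enhancement
#' \eqn{\epsilon = p v_- T_{1I} \frac{1}{1 + v_+ T_{1I}} |\gamma_S|/\gamma_I}
#' and its multiplicative approximation (the \eqn{v_+ T_{1I} \ll 1} limit,
#' which drops the parenthesized factor). The product \code{v_plus * T1I} is
#' returned so callers can check the validity of the approximation.
#'
#' @param p electronic non-saturation factor (dimensionless).
#' @param pv_minus polarization-transfer rate p*v- (1/s).
#' @param v_plus microwave-driven nuclear relaxation rate (1/s).
#' @param T1I nuclear spin-lattice relaxation time (s), > 0.
#' @param gamma_ratio |gamma_S|/gamma_I; defaults to the electron/proton value.
#' @return List with \code{exact}, \code{multiplicative} and
#'   \code{v_plus_T1I}.
#' @export
enhancement_from_rates <- function(p, pv_minus, v_plus, T1I,
                                   gamma_ratio = .const$gamma_ratio_eH) {
  .stopifnot_finite(p = p, pv_minus = pv_minus, v_plus = v_plus, T1I = T1I)
  if (T1I <= 0) stop("invalid parameter: T1I must be > 0", call. = FALSE)
  if (gamma_ratio <= 0) stop("invalid parameter: gamma_ratio must be > 0", call. = FALSE)
  mult <- pv_minus * T1I * gamma_ratio
  list(exact = mult / (1 + v_plus * T1I),
       multiplicative = mult,
       v_plus_T1I = v_plus * T1I)
}
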