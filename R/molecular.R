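#' Leakage factor from nuclear relaxation times
#'
#' \eqn{f = 1 - T_{1I}/T_{1I}^0}: compares the nuclear spin-lattice times
#' with (\code{T1I}) and without (\code{T1I0}) the polarizing agent.
#'
#' @param T1I nuclear T1 with radical (s), > 0.
#' @param T1I0 nuclear T1 without radical (s), >= T1I.
#' @return leakage factor in (0, 1].
#' @examples
#' leakage_factor(44e-3, 580e-3)  # 0.92
#' @export
leakage_factor <- function(T1I, T1I0) {
  .stopifnot_finite(T1I = T1I, T1I0 = T1I0)
  if (T1I <= 0 || T1I0 <= 0) stop("invalid parameter: T1 times must be > 0", call. = FALSE)
  if (any(T1I > T1I0))
    stop("invalid parameter: T1I must not exceed T1I0", call. = FALSE)
  1 - T1I / T1I0
}

#' Overhauser coupling factor from the fitted OE amplitude
#'
#' \eqn{c = (\sigma_{OE}/f)\,(\gamma_I/|\gamma_S|)}. The fitted amplitude
#' multiplies the absolute saturation profile, so dividing by the leakage
#' factor and the gyromagnetic ratio recovers the coupling factor.
#'
#' @param sigma_OE fitted Overhauser amplitude (dimensionless).
#' @param f leakage factor, > 0.
#' @param gamma_ratio |gamma_S|/gamma_I.
#' @return coupling factor (dimensionless; multiply by 1000 for per-mille).
#' @examples
#' f <- leakage_factor(44e-3, 580e-3)
#' 1e3 * coupling_factor(2.43, f)  # ~ 3.99 per-mille
#' @export
coupling_factor <- function(sigma_OE, f, gamma_ratio = .const$gamma_ratio_eH) {
  .stopifnot_finite(sigma_OE = sigma_OE, f = f)
  if (any(f <= 0)) stop("invalid parameter: f must be > 0", call. = FALSE)
  (sigma_OE / f) / gamma_ratio
}

#' Dipolar strength-relaxation product from the fitted SE amplitude
#'
#' \eqn{\langle\delta^2\rangle T_{1I} = \sigma_{SE}\,\gamma_I/|\gamma_S|}.
#'
#' @param sigma_SE fitted solid-effect amplitude (1/s), >= 0.
#' @param gamma_ratio |gamma_S|/gamma_I.
#' @return \eqn{\langle\delta^2\rangle T_{1I}} (1/s).
#' @examples
#' delta2_T1I(1.51e12) / 1e9  # ~ 2.29 ns^-1
#' @export
delta2_T1I <- function(sigma_SE, gamma_ratio = .const$gamma_ratio_eH) {
  .stopifnot_finite(sigma_SE = sigma_SE)
  if (any(sigma_SE < 0)) stop("invalid parameter: sigma_SE must be >= 0", call. = FALSE)
  sigma_SE / gamma_ratio
}

#' Effective contact distance of the FFHS model
#'
#' Inverts the dipolar scale for the contact distance:
#' \eqn{\langle\delta^2\rangle = (\sigma_{SE}\gamma_I/|\gamma_S|)/T_{1I}} and
#' \eqn{b = [D_{dip}^2 (6\pi/5) N / (3\langle\delta^2\rangle)]^{1/3}}.
#'
#' @param sigma_SE fitted SE amplitude (1/s).
#' @param T1I nuclear T1 with radical (s).
#' @param N electron number density (nm^-3).
#' @param gamma_ratio |gamma_S|/gamma_I.
#' @param D_dip dipolar constant (rad/s nm^3).
#' @return contact distance b (nm).
#' @examples
#' contact_distance(1.51e12, 44e-3, 1 / 26)  # ~ 0.61 nm
#' @export
contact_distance <- function(sigma_SE, T1I, N,
                             gamma_ratio = .const$gamma_ratio_eH,
                             D_dip = dipolar_constant()) {
  .stopifnot_finite(sigma_SE = sigma_SE, T1I = T1I, N = N)
  if (any(c(sigma_SE, T1I, N) <= 0))
    stop("invalid parameter: all inputs must be > 0", call. = FALSE)
  d2 <- delta2_T1I(sigma_SE, gamma_ratio) / T1I
  (D_dip^2 * (6 * pi / 5) * N / (3 * d2))^(1 / 3)
}

#' FFHS diffusion coefficient from contact distance and timescale
#'
#' \eqn{D = b^2/\tau_{ffhs}}, reported in nm^2/us.
#'
#' @param b contact distance (nm), > 0.
#' @param tau_ffhs diffusive timescale (s), > 0.
#' @return diffusion coefficient (nm^2/us).
#' @examples
#' diffusion_constant(0.875, 15.3e-9)  # ~ 50 nm^2/us
#' @export
diffusion_constant <- function(b, tau_ffhs) {
  .stopifnot_finite(b = b, tau_ffhs = tau_ffhs)
  if (any(c(b, tau_ffhs) <= 0)) stop("invalid parameter: inputs must be > 0", call. = FALSE)
  b^2 / (tau_ffhs * 1e6)
}

#' Electron number density from labeling ratio and molecular volume
#'
#' One labeled molecule per \code{molar_ratio} host molecules of volume
#' \code{molecular_volume} gives \eqn{N = 1/(ratio \times volume)}; also
#' returned as a molar concentration.
#'
#' @param molar_ratio host molecules per labeled molecule, > 0.
#' @param molecular_volume host molecular volume (nm^3), > 0.
#' @return list with \code{N} (nm^-3) and \code{concentration_mM}.
#' @examples
#' number_density(20, 1.3)$concentration_mM  # ~ 64 mM
#' @export
number_density <- function(molar_ratio, molecular_volume) {
  .stopifnot_finite(molar_ratio = molar_ratio,
                    molecular_volume = molecular_volume)
  if (molar_ratio <= 0 || molecular_volume <= 0)
    stop("invalid parameter: inputs must be > 0", call. = FALSE)
  N <- 1 / (molar_ratio * molecular_volume)    # nm^-3
  avogadro <- 6.02214076e23
  list(N = N, concentration_mM = N * 1e24 / avogadro * 1e3)
}

#' Full molecular-parameter chain from the fitted DNP amplitudes
#'
#' Convenience wrapper running the whole derivation: leakage factor,
#' coupling factor, \eqn{\langle\delta^2\rangle T_{1I}}, contact distance
#' and FFHS diffusion coefficient.
#'
#' @param sigma_OE Overhauser amplitude (dimensionless).
#' @param sigma_SE solid-effect amplitude (1/s).
#' @param tau_ffhs fitted translational timescale (s).
#' @param T1I,T1I0 nuclear T1 with and without radical (s).
#' @param N electron number density (nm^-3).
#' @param gamma_ratio |gamma_S|/gamma_I.
#' @return one-row data frame with columns \code{f}, \code{c_permille},
#'   \code{delta2_T1I_per_ns}, \code{b_nm}, \code{D_nm2_us}.
#' @export
derive_molecular_params <- function(sigma_OE, sigma_SE, tau_ffhs, T1I, T1I0,
                                    N, gamma_ratio = .const$gamma_ratio_eH) {
  f <- leakage_factor(T1I, T1I0)
  b <- contact_distance(sigma_SE, T1I, N, gamma_ratio)
  data.frame(
    f = f,
    c_permille = 1e3 * coupling_factor(sigma_OE, f, gamma_ratio),
    delta2_T1I_per_ns = delta2_T1I(sigma_SE, gamma_ratio) / 1e9,
    b_nm = b,
    D_nm2_us = diffusion_constant(b, tau_ffhs)
  )
}
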