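#' Electronic spin-system parameters
#'
#' Bundles the static field, microwave field and electronic relaxation times
#' of the polarizing agent, together with the derived angular frequencies.
#' The microwave amplitude \code{B1_G} (in Gauss) is interpreted as the
#' rotating-frame amplitude, so the nutation frequency is
#' \eqn{\omega_1 = g_0 \mu_B B_1 / \hbar} with no further factor of 1/2.
#'
#' @param B0 static magnetic field (T).
#' @param B1_G microwave field amplitude (Gauss).
#' @param T1e electronic spin-lattice relaxation time (s).
#' @param T2e electronic spin-spin relaxation time (s).
#' @param g0 isotropic g value used to convert \code{B1_G} to \eqn{\omega_1}.
#' @param omega_I nuclear Larmor angular frequency (rad/s). Defaults to the
#'   proton value \eqn{\gamma_H B_0}; at 9.403 T this is \eqn{2\pi \cdot 400}
#'   MHz, which sets the solid-effect matching offsets.
#'
#' @return An object of class \code{"spin_system"}: a list with the inputs
#'   plus \code{omega1}, \code{R1}, \code{R2} and \code{omega_I} (rad/s).
#' @examples
#' sp <- spin_system(B0 = 9.403, B1_G = 5.5, T1e = 100e-9, T2e = 20e-9)
#' sp$omega1 / (2 * pi * 1e6)  # nutation frequency in MHz
#' @export
spin_system <- function(B0, B1_G, T1e, T2e, g0 = 2.0023, omega_I = NULL) {
  .stopifnot_finite(B0 = B0, B1_G = B1_G, T1e = T1e, T2e = T2e, g0 = g0)
  if (T1e <= 0 || T2e <= 0) stop("invalid parameter: T1e and T2e must be > 0", call. = FALSE)
  if (B1_G < 0) stop("invalid parameter: B1_G must be >= 0", call. = FALSE)
  if (is.null(omega_I)) omega_I <- .const$gamma_H * B0
  .stopifnot_finite(omega_I = omega_I)
  structure(list(
    B0 = B0, B1_G = B1_G, T1e = T1e, T2e = T2e, g0 = g0,
    omega1 = g0 * .const$mu_B / .const$hbar * B1_G * 1e-4,
    R1 = 1 / T1e, R2 = 1 / T2e,
    omega_I = omega_I
  ), class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system>\n")
  cat(sprintf("  B0 = %.4f T, B1 = %g G (omega1/2pi = %.3f MHz)\n",
              x$B0, x$B1_G, x$omega1 / (2 * pi * 1e6)))
  cat(sprintf("  T1e = %g ns, T2e = %g ns, omega_I/2pi = %.1f MHz\n",
              x$T1e * 1e9, x$T2e * 1e9, x$omega_I / (2 * pi * 1e6)))
  invisible(x)
}

#' Principal g tensor of the radical
#'
#' @param gxx,gyy,gzz principal values in the molecular frame.
#' @return Object of class \code{"g_tensor"} with the principal values and the
#'   isotropic average \code{g0}. Values far from the free-electron region
#'   (2 +/- 0.1) trigger a warning but are accepted.
#' @examples
#' g_tensor(2.00755, 2.00555, 2.0023)
#' @export
g_tensor <- function(gxx, gyy, gzz) {
  .stopifnot_finite(gxx = gxx, gyy = gyy, gzz = gzz)
  if (any(abs(c(gxx, gyy, gzz) - 2) > 0.1))
    warning("g values far from 2: check units/order of the principal values")
  structure(list(gxx = gxx, gyy = gyy, gzz = gzz,
                 g0 = (gxx + gyy + gzz) / 3),
            class = "g_tensor")
}

#' Isotropic rotational diffusion of the polarizing agent
#'
#' The rank-2 tumbling time follows the standard slow-motional convention
#' \eqn{\tau_{rot} = 1/(6 D_{rot})} (eigenvalue \eqn{D_{rot} L(L+1)} at L = 2).
#'
#' @param tau_rot rank-2 rotational correlation time (s), or \code{NULL}.
#' @param D_rot rotational diffusion coefficient (rad^2/s), or \code{NULL}.
#'   Exactly one of the two must be given.
#' @return Object of class \code{"rotational_diffusion"} with both fields.
#' @export
rotational_diffusion <- function(tau_rot = NULL, D_rot = NULL) {
  if (is.null(tau_rot) == is.null(D_rot))
    stop("give exactly one of tau_rot or D_rot", call. = FALSE)
  if (is.null(D_rot)) {
    .stopifnot_finite(tau_rot = tau_rot)
    if (tau_rot <= 0) stop("tau_rot must be > 0", call. = FALSE)
    D_rot <- 1 / (6 * tau_rot)
  } else {
    .stopifnot_finite(D_rot = D_rot)
    if (D_rot <= 0) stop("D_rot must be > 0", call. = FALSE)
    tau_rot <- 1 / (6 * D_rot)
  }
  structure(list(tau_rot = tau_rot, D_rot = D_rot),
            class = "rotational_diffusion")
}
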