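#' Solid-effect rate profile under slow tumbling, static dipolar coupling
#'
#' The "solid" branch: the electron-nucleus dipolar coupling is constant in
#' time while the radical tumbles. Per offset the reduced route inverts the
#' ntot x ntot matrices \eqn{P} (the saturation matrix with the nuclear
#' Larmor shift \eqn{+i\omega_I} on its diagonal) and \eqn{P_0}, giving
#' \deqn{v_+ = -\delta^2\omega_1^2\,
#'   \mathrm{Re}\{(R_1 + i\omega_I)^{-2} [P^{-1}]_{11}\},}
#' \deqn{p v_- = -\delta^2\omega_1^2\, \mathrm{Im}\{(R_1 + i\omega_I)^{-1}
#'   [P^{-1}(R_2^{-1}\Delta + \Delta(R_2 + i\omega_I)^{-1})P_0^{-1}]_{11}\},}
#' with scalar \eqn{R_1 + i\omega_I} (the detected L = 0 diagonal entry).
#' The thermal rate \eqn{R_{1I}^A = \delta^2\mathrm{Re}\{(R_1+i\omega_I)^{-1}\}}
#' is unaffected by the g anisotropy. \code{method = "full"} inverts the
#' 3ntot x 3ntot coherence matrix B instead; the two routes agree.
#'
#' @param offsets offsets from the isotropic-g resonance (rad/s).
#' @param ops an [sle_operators()]; its spin system needs \code{omega_I > 0}.
#' @param delta2 squared dipolar coupling ((rad/s)^2).
#' @param method "reduced" (default) or "full".
#' @return data frame of class \code{"rate_profile"}: columns \code{offset},
#'   \code{v_plus}, \code{pv_minus}, \code{R1IA}, \code{s}, \code{p},
#'   \code{v_minus} (= pv_minus / p).
#' @export
se_rates_slow_solid <- function(offsets, ops, delta2,
                                method = c("reduced", "full")) {
  method <- match.arg(method)
  .stopifnot_finite(offsets = offsets, delta2 = delta2)
  spin <- ops$spin
  if (spin$omega_I <= 0) stop("invalid parameter: omega_I must be > 0", call. = FALSE)
  n <- ops$basis$ntot
  w1 <- spin$omega1
  wI <- spin$omega_I
  r1I <- spin$R1 + 1i * wI            # detected (L = 0) diagonal entry
  e1 <- c(1, numeric(n - 1))
  r2inv <- 1 / ops$r2d
  r2Iinv <- 1 / (ops$r2d + 1i * wI)
  R1IA <- delta2 * Re(1 / r1I)
  out <- vapply(offsets, function(d) {
    Dm <- ops$Delta_m(d)
    P0 <- .sle_P(ops, d, 0)
    x0 <- solve(P0, e1)
    sfac <- w1^2 * spin$T1e * x0[1]
    if (method == "reduced") {
      P <- .sle_P(ops, d, wI)
      p11 <- solve(P, e1)[1]
      vp <- -delta2 * w1^2 * Re(p11 / r1I^2)
      M <- r2inv * Dm + Dm %*% diag(r2Iinv, n)
      val <- solve(P, M %*% x0)[1]
      pvm <- -delta2 * w1^2 * Im(val / r1I)
    } else {
      B <- .sle_B_full(ops, d, wI)
      Binv <- solve(B)
      iz <- 2 * n + 1                  # first (0,0) row of the z block
      vp <- delta2 * Re(Binv[iz, iz]) - R1IA
      rzx <- Binv[iz, 1:n]
      rzy <- Binv[iz, (n + 1):(2 * n)]
      val <- sum((rzx + rzy %*% (r2inv * Dm)) * x0)
      pvm <- -delta2 * w1 * Im(val)
    }
    c(vp, pvm, sfac)
  }, numeric(3))
  .rate_profile(offsets, out[1, ], out[2, ], R1IA, out[3, ])
}

#' Solid-effect rate profile under slow tumbling, FFHS-modulated coupling
#'
#' The liquid branch: translational diffusion modulates the dipolar
#' coupling. The inverse of the 3ntot x 3ntot coherence matrix B is replaced
#' by the matrix spectral density \eqn{Q = j_{11}(B)}, evaluated by
#' eigendecomposition, and the rates are read from the detected row of the
#' z block:
#' \deqn{v_+ = \langle\delta^2\rangle\,\mathrm{Re}\{[[Q]_{zz}]_{11}\} - R_{1I}^A,
#' \quad p v_- = -\langle\delta^2\rangle\,\omega_1\,
#'   \mathrm{Im}\{[([Q]_{zx} + [Q]_{zy} R_2^{-1}\Delta) P_0^{-1}]_{11}\},}
#' with \eqn{R_{1I}^A = \langle\delta^2\rangle\,
#' \mathrm{Re}\{j_{11}(R_1 + i\omega_I)\}} (the scalar form; the z block
#' decouples at \eqn{\omega_1 = 0}). With \code{j11 = function(s) 1/s} the
#' static-coupling profile is recovered exactly.
#'
#' A near-degenerate eigendecomposition triggers one retry with a
#' 1e-8-relative perturbation of the offending offset before erroring:
#' B is non-normal and exact degeneracies occur only on measure-zero
#' parameter sets.
#'
#' @param offsets offsets (rad/s).
#' @param ops an [sle_operators()].
#' @param avg_delta2 averaged squared dipolar strength ((rad/s)^2).
#' @param j11 reduced spectral density function, e.g.
#'   \code{function(s) j11_ffhs(s, tau)}.
#' @return data frame of class \code{"rate_profile"}, as in
#'   [se_rates_slow_solid()].
#' @export
se_rates_slow_liquid <- function(offsets, ops, avg_delta2, j11) {
  .stopifnot_finite(offsets = offsets, avg_delta2 = avg_delta2)
  spin <- ops$spin
  if (spin$omega_I <= 0) stop("invalid parameter: omega_I must be > 0", call. = FALSE)
  n <- ops$basis$ntot
  w1 <- spin$omega1
  wI <- spin$omega_I
  e1 <- c(1, numeric(n - 1))
  r2inv <- 1 / ops$r2d
  R1IA <- avg_delta2 * Re(j11(spin$R1 + 1i * wI))
  iz <- 2 * n + 1
  one_offset <- function(d) {
    B <- .sle_B_full(ops, d, wI)
    e <- eigen(B)
    U <- e$vectors
    if (rcond(U) < 1e-8) stop("numerical degeneracy", call. = FALSE)
    lam <- e$values
    lam[Re(lam) < 0] <- 1i * Im(lam[Re(lam) < 0])
    # only the detected row of Q = U diag(j11(lam)) U^-1 is needed
    qrow <- (U[iz, ] * j11(lam)) %*% solve(U)
    P0 <- .sle_P(ops, d, 0)
    x0 <- solve(P0, e1)
    sfac <- w1^2 * spin$T1e * x0[1]
    Dm <- ops$Delta_m(d)
    vp <- avg_delta2 * Re(qrow[iz]) - R1IA
    val <- sum((qrow[1:n] + qrow[(n + 1):(2 * n)] %*% (r2inv * Dm)) * x0)
    pvm <- -avg_delta2 * w1 * Im(val)
    c(vp, pvm, sfac)
  }
  out <- vapply(offsets, function(d) {
    tryCatch(one_offset(d), error = function(err) {
      if (grepl("degeneracy", conditionMessage(err)))
        one_offset(d * (1 + 1e-8) + (d == 0) * 1e-8 * max(abs(offsets)))
      else stop(err)
    })
  }, numeric(3))
  .rate_profile(offsets, out[1, ], out[2, ], R1IA, out[3, ])
}

.rate_profile <- function(offsets, v_plus, pv_minus, R1IA, s) {
  p <- 1 - s
  structure(data.frame(offset = offsets, v_plus = v_plus,
                       pv_minus = pv_minus, R1IA = R1IA,
                       s = s, p = p, v_minus = pv_minus / p),
            class = c("rate_profile", "data.frame"))
}

#' Mixed Overhauser + solid-effect DNP spectrum
#'
#' Assembles the enhancement profile
#' \deqn{\epsilon(\Delta) = -\sigma_{OE}\, s(\Delta - \Delta_0)
#'   + \sigma_{SE}\, \frac{p v_-}{\langle\delta^2\rangle}(\Delta - \Delta_0),}
#' where \eqn{s} is the power-broadened electronic saturation profile and
#' \eqn{p v_-/\langle\delta^2\rangle} the solid-effect transfer timescale.
#' The stored \eqn{\sigma_{OE}} is a positive magnitude; the explicit minus
#' sign encodes the dipolar (negative) sign of the Overhauser feature, so
#' the profile shows a negative dip near zero offset and a positive
#' solid-effect peak near \eqn{+\omega_I}.
#'
#' @param offsets offsets (rad/s).
#' @param ops an [sle_operators()].
#' @param sigma_OE Overhauser amplitude (dimensionless, stored positive for
#'   a dipolar-dominated coupling).
#' @param sigma_SE solid-effect amplitude (1/s).
#' @param j11 reduced spectral density function (liquid branch). Use
#'   \code{function(s) 1/s} for a static coupling.
#' @param shift horizontal offset correction (rad/s).
#' @return data frame with columns \code{offset}, \code{enhancement},
#'   \code{oe}, \code{se}.
#' @export
dnp_spectrum_model <- function(offsets, ops, sigma_OE, sigma_SE, j11,
                               shift = 0) {
  .stopifnot_finite(offsets = offsets, sigma_OE = sigma_OE,
                    sigma_SE = sigma_SE, shift = shift)
  prof <- se_rates_slow_liquid(offsets - shift, ops, avg_delta2 = 1, j11)
  oe <- -sigma_OE * prof$s
  se <- sigma_SE * prof$pv_minus   # pv_minus per unit avg_delta2: units s
  data.frame(offset = offsets, enhancement = oe + se, oe = oe, se = se)
}
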