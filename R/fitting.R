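#' Convert a field axis to an offset axis
#'
#' DNP and EPR experiments sweep the static field at constant microwave
#' frequency; calculations use a fixed field and a variable offset. The
#' conversion is \eqn{\Delta(B) = g_{ref}\mu_B B/\hbar - 2\pi\,\nu_{mw}};
#' any residual reference ambiguity is absorbed by the fitted horizontal
#' shift. At g ~ 2 the slope is about \eqn{2\pi \cdot 28} GHz/T.
#'
#' @param field_T field axis (T).
#' @param mw_freq microwave frequency (Hz), > 0.
#' @param g_ref reference g value.
#' @return offset axis (rad/s), monotone in the field.
#' @export
convert_field_to_offset <- function(field_T, mw_freq, g_ref = 2.0023) {
  .stopifnot_finite(field_T = field_T, mw_freq = mw_freq, g_ref = g_ref)
  if (mw_freq <= 0) stop("mw_freq must be > 0", call. = FALSE)
  g_ref * .const$mu_B / .const$hbar * field_T - 2 * pi * mw_freq
}

.mhz <- function(x) x / (2 * pi * 1e6)
.rad <- function(x) x * 2 * pi * 1e6

# Profile out linear amplitudes: given model columns M (n x k) and data y,
# the optimal coefficients solve the normal equations; residual returned.
.varpro <- function(M, y, coef_fixed = NULL) {
  if (!is.null(coef_fixed)) {
    free <- is.na(coef_fixed)
    y <- y - as.matrix(M[, !free, drop = FALSE]) %*% coef_fixed[!free]
    if (!any(free)) {
      cf <- coef_fixed
      return(list(coef = cf, resid = as.numeric(y)))
    }
    Mf <- M[, free, drop = FALSE]
    cf_free <- qr.coef(qr(Mf), y)
    cf <- coef_fixed
    cf[free] <- cf_free
    return(list(coef = cf, resid = as.numeric(y - Mf %*% cf_free)))
  }
  cf <- qr.coef(qr(M), y)
  list(coef = cf, resid = as.numeric(y - M %*% cf))
}

.new_fit_result <- function(params, fixed, resid, n_evals, success, model) {
  structure(list(params = params, fixed = fixed,
                 residual_norm = sqrt(sum(resid^2)),
                 residuals = resid,
                 n_evals = n_evals, success = success, model = model),
            class = "sednp_fit")
}

#' @export
print.sednp_fit <- function(x, ...) {
  cat("<sednp_fit>", if (x$success) "(converged)" else "(NOT converged)", "\n")
  for (nm in names(x$params)) {
    tag <- if (isTRUE(x$fixed[nm])) " [fixed]" else ""
    cat(sprintf("  %-10s %.6g%s\n", nm, x$params[[nm]], tag))
  }
  cat(sprintf("  residual norm %.4g after %d evaluations\n",
              x$residual_norm, x$n_evals))
  invisible(x)
}

#' Fit a derivative cw-EPR spectrum
#'
#' Nonlinear least squares of the slow-tumbling derivative model against a
#' measured (or synthetic) derivative spectrum. Free parameters are the
#' g-anisotropy frequencies \code{gamma02} and \code{gamma22} (MHz), the
#' tumbling time \code{tau_rot} (ns), the dispersion mixing angle \code{phi}
#' (degrees) and the horizontal \code{shift} (MHz); the overall amplitude is
#' profiled out by linear least squares at every step, so the fit is
#' invariant to rescaling of the data. Any subset can be held fixed.
#' Optimization uses Levenberg-Marquardt with box bounds and a small
#' log-spaced multi-start over \code{tau_rot} (the landscape can be rugged).
#'
#' @param data a spectrum as returned by [read_spectrum()] (axis in MHz), or
#'   a data frame with columns \code{axis} and \code{value}.
#' @param B0 static field (T).
#' @param init named list of starting values (units as above); defaults:
#'   gamma02 = -373, gamma22 = 107, tau_rot = 3, phi = 0, shift = 0.
#' @param fixed named list of parameters to fix at the given values.
#' @param lmax SLE truncation order.
#' @param B1_G,T1e,T2e spin parameters held fixed during the fit (low-power
#'   cw-EPR defaults).
#' @param bounds named list overriding default box bounds, each element
#'   \code{c(lower, upper)}.
#' @param n_starts number of tau_rot multi-start points.
#' @return A \code{"sednp_fit"} object; \code{$params} holds gamma02 and
#'   gamma22 (MHz), tau_rot (ns), phi (deg), shift (MHz) and the profiled
#'   \code{amplitude}; \code{$model(axis_MHz)} replays the fitted curve.
#' @export
fit_epr <- function(data, B0, init = list(), fixed = list(), lmax = 10,
                    B1_G = 0.02, T1e = 100e-9, T2e = 20e-9,
                    bounds = list(), n_starts = 3) {
  d <- .as_spectrum_df(data)
  spin <- spin_system(B0, B1_G, T1e, T2e)
  basis <- sle_basis(lmax)
  defaults <- list(gamma02 = -373, gamma22 = 107, tau_rot = 3,
                   phi = 0, shift = 0)
  init <- utils::modifyList(defaults, init)
  b0 <- list(gamma02 = c(-1000, 1000), gamma22 = c(-1000, 1000),
             tau_rot = c(0.01, 100), phi = c(-15, 15), shift = c(-100, 100))
  b0 <- utils::modifyList(b0, bounds)
  pnames <- names(defaults)
  is_fixed <- stats::setNames(pnames %in% names(fixed), pnames)
  theta_full <- unlist(init)
  theta_full[names(fixed)] <- unlist(fixed)

  offsets <- .rad(d$axis)
  n_evals <- 0L
  model_cols <- function(theta) {
    n_evals <<- n_evals + 1L
    rot <- rotational_diffusion(tau_rot = theta[["tau_rot"]] * 1e-9)
    ops <- sle_operators(basis, spin, rot,
                         .rad(theta[["gamma02"]]), .rad(theta[["gamma22"]]))
    m <- epr_derivative_spectrum(offsets - .rad(theta[["shift"]]), ops,
                                 phi = theta[["phi"]] * pi / 180)
    matrix(m, ncol = 1)
  }
  to_internal <- function(th) { th["tau_rot"] <- log(th["tau_rot"]); th }
  from_internal <- function(th) { th["tau_rot"] <- exp(th["tau_rot"]); th }
  theta_int <- to_internal(theta_full)
  resid_fn <- function(par_free) {
    th <- theta_int
    th[!is_fixed] <- par_free
    .varpro(model_cols(from_internal(th)), d$value)$resid
  }
  lower <- vapply(pnames, function(p) b0[[p]][1], numeric(1))
  upper <- vapply(pnames, function(p) b0[[p]][2], numeric(1))
  lower["tau_rot"] <- log(lower["tau_rot"]); upper["tau_rot"] <- log(upper["tau_rot"])

  starts <- list(theta_int)
  if (!is_fixed[["tau_rot"]] && n_starts > 1) {
    taus <- exp(seq(log(1), log(15), length.out = n_starts - 1))
    for (tv in taus) {
      th <- theta_int; th["tau_rot"] <- log(tv)
      starts <- c(starts, list(th))
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st[!is_fixed], fn = resid_fn,
                         lower = lower[!is_fixed], upper = upper[!is_fixed],
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("EPR fit failed from every start", call. = FALSE)
  th <- theta_int
  th[!is_fixed] <- best$par
  th <- from_internal(th)
  vp <- .varpro(model_cols(th), d$value)
  params <- c(as.list(th), amplitude = unname(vp$coef[1]))
  model <- function(axis_MHz) {
    rot <- rotational_diffusion(tau_rot = th[["tau_rot"]] * 1e-9)
    ops <- sle_operators(basis, spin, rot,
                         .rad(th[["gamma02"]]), .rad(th[["gamma22"]]))
    params$amplitude *
      epr_derivative_spectrum(.rad(axis_MHz) - .rad(th[["shift"]]), ops,
                              phi = th[["phi"]] * pi / 180)
  }
  .new_fit_result(params, is_fixed, vp$resid, n_evals,
                  best$info %in% 1:4, model)
}

#' Fit a DNP enhancement profile
#'
#' Decomposes a measured (or synthetic) DNP spectrum into its Overhauser
#' and solid-effect components by fitting
#' \eqn{\epsilon(\Delta) = -\sigma_{OE} s(\Delta - \Delta_0) +
#' \sigma_{SE}\, p v_-/\langle\delta^2\rangle(\Delta - \Delta_0)}.
#' The g tensor and tumbling time come from a preceding EPR fit and stay
#' fixed. Nonlinear parameters are \code{tau_ffhs} (ns), \code{T1e} (ns) and
#' \code{shift} (MHz); the amplitudes \code{sigma_OE} (dimensionless) and
#' \code{sigma_SE} (1/ps) are linear and profiled out at every step (fix
#' either via \code{fixed} to constrain the decomposition).
#'
#' @param data spectrum (axis MHz, values enhancement units).
#' @param B0 static field (T).
#' @param gamma02,gamma22 anisotropy frequencies (MHz), fixed.
#' @param tau_rot tumbling time (ns), fixed.
#' @param init named list: starting tau_ffhs, T1e (ns), shift (MHz).
#' @param fixed named list of parameters to fix (\code{tau_ffhs}, \code{T1e},
#'   \code{shift}, \code{sigma_OE}, \code{sigma_SE}).
#' @param lmax SLE truncation order.
#' @param B1_G,T2e spin parameters held fixed (high-power DNP defaults).
#' @param bounds named list overriding default box bounds.
#' @param n_starts number of tau_ffhs multi-start points.
#' @return A \code{"sednp_fit"}; \code{$params} holds tau_ffhs (ns), T1e
#'   (ns), shift (MHz), sigma_OE (dimensionless) and sigma_SE (1/ps).
#' @export
fit_dnp <- function(data, B0, gamma02, gamma22, tau_rot,
                    init = list(), fixed = list(), lmax = 10,
                    B1_G = 5.5, T2e = 20e-9, bounds = list(), n_starts = 2) {
  d <- .as_spectrum_df(data)
  basis <- sle_basis(lmax)
  defaults <- list(tau_ffhs = 5, T1e = 120, shift = 0)
  init <- utils::modifyList(defaults, init)
  b0 <- list(tau_ffhs = c(0.1, 100), T1e = c(10, 2000), shift = c(-100, 100))
  b0 <- utils::modifyList(b0, bounds)
  pnames <- names(defaults)
  nl_fixed <- stats::setNames(pnames %in% names(fixed), pnames)
  theta_full <- unlist(init)
  for (p in intersect(names(fixed), pnames)) theta_full[p] <- fixed[[p]]
  sig_fix <- c(sigma_OE = NA_real_, sigma_SE = NA_real_)
  if ("sigma_OE" %in% names(fixed)) sig_fix["sigma_OE"] <- fixed$sigma_OE
  if ("sigma_SE" %in% names(fixed)) sig_fix["sigma_SE"] <- fixed$sigma_SE * 1e12

  offsets <- .rad(d$axis)
  n_evals <- 0L
  model_cols <- function(theta) {
    n_evals <<- n_evals + 1L
    spin <- spin_system(B0, B1_G, theta[["T1e"]] * 1e-9, T2e)
    rot <- rotational_diffusion(tau_rot = tau_rot * 1e-9)
    ops <- sle_operators(basis, spin, rot, .rad(gamma02), .rad(gamma22))
    tau <- theta[["tau_ffhs"]] * 1e-9
    prof <- se_rates_slow_liquid(offsets - .rad(theta[["shift"]]), ops,
                                 avg_delta2 = 1,
                                 j11 = function(s) j11_ffhs(s, tau))
    cbind(oe = -prof$s, se = prof$pv_minus)
  }
  to_internal <- function(th) { th["tau_ffhs"] <- log(th["tau_ffhs"]); th }
  from_internal <- function(th) { th["tau_ffhs"] <- exp(th["tau_ffhs"]); th }
  theta_int <- to_internal(theta_full)
  resid_fn <- function(par_free) {
    th <- theta_int
    th[!nl_fixed] <- par_free
    .varpro(model_cols(from_internal(th)), d$value,
            coef_fixed = sig_fix)$resid
  }
  lower <- vapply(pnames, function(p) b0[[p]][1], numeric(1))
  upper <- vapply(pnames, function(p) b0[[p]][2], numeric(1))
  lower["tau_ffhs"] <- log(lower["tau_ffhs"])
  upper["tau_ffhs"] <- log(upper["tau_ffhs"])

  starts <- list(theta_int)
  if (!nl_fixed[["tau_ffhs"]] && n_starts > 1) {
    for (tv in exp(seq(log(3), log(15), length.out = n_starts - 1))) {
      th <- theta_int; th["tau_ffhs"] <- log(tv)
      starts <- c(starts, list(th))
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st[!nl_fixed], fn = resid_fn,
                         lower = lower[!nl_fixed], upper = upper[!nl_fixed],
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("DNP fit failed from every start", call. = FALSE)
  th <- theta_int
  th[!nl_fixed] <- best$par
  th <- from_internal(th)
  vp <- .varpro(model_cols(th), d$value, coef_fixed = sig_fix)
  params <- c(as.list(th),
              sigma_OE = unname(vp$coef[1]),
              sigma_SE = unname(vp$coef[2]) * 1e-12)   # report 1/ps
  fixed_flags <- c(nl_fixed, sigma_OE = "sigma_OE" %in% names(fixed),
                   sigma_SE = "sigma_SE" %in% names(fixed))
  model <- function(axis_MHz) {
    spin <- spin_system(B0, B1_G, th[["T1e"]] * 1e-9, T2e)
    rot <- rotational_diffusion(tau_rot = tau_rot * 1e-9)
    ops <- sle_operators(basis, spin, rot, .rad(gamma02), .rad(gamma22))
    tau <- th[["tau_ffhs"]] * 1e-9
    dnp_spectrum_model(.rad(axis_MHz), ops, sigma_OE = params$sigma_OE,
                       sigma_SE = params$sigma_SE * 1e12,
                       j11 = function(s) j11_ffhs(s, tau),
                       shift = .rad(th[["shift"]]))
  }
  .new_fit_result(params, fixed_flags, vp$resid, n_evals,
                  best$info %in% 1:4, model)
}

.as_spectrum_df <- function(data) {
  if (inherits(data, "spectrum_data") || is.data.frame(data)) {
    if (!all(c("axis", "value") %in% names(data)))
      stop("spectrum needs 'axis' and 'value' columns", call. = FALSE)
    d <- data.frame(axis = data$axis, value = data$value)
  } else stop("unsupported spectrum input", call. = FALSE)
  .stopifnot_finite(axis = d$axis, value = d$value)
  d
}
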