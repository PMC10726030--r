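#' Physical constants used throughout the package
#'
#' Returns the CODATA values used internally. All frequencies in the package
#' are angular (rad/s); user-facing spectrum axes are ordinary frequency (MHz).
#'
#' @return A named list with elements
#'   \describe{
#'     \item{mu_B}{Bohr magneton (J/T)}
#'     \item{hbar}{reduced Planck constant (J s)}
#'     \item{gamma_e}{free-electron gyromagnetic ratio magnitude (rad/s/T)}
#'     \item{gamma_H}{proton gyromagnetic ratio (rad/s/T)}
#'     \item{mu0_over_4pi}{magnetic constant over 4 pi (T m/A)}
#'     \item{gamma_ratio_eH}{|gamma_e|/gamma_H, the free-electron/proton ratio}
#'   }
#' @export
physical_constants <- function() {
  list(
    mu_B          = 9.2740100783e-24,
    hbar          = 1.054571817e-34,
    gamma_e       = 1.76085963023e11,
    gamma_H       = 2.6752218744e8,
    mu0_over_4pi  = 1e-7,
    gamma_ratio_eH = 658.21
  )
}

.const <- physical_constants()

.stopifnot_finite <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (!is.numeric(x) && !is.complex(x))
      stop("invalid parameter '", nm[i], "': not numeric", call. = FALSE)
    if (any(!is.finite(x)))
      stop("invalid parameter '", nm[i], "': non-finite value", call. = FALSE)
  }
  invisible(TRUE)
}
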