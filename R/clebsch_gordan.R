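#' Clebsch-Gordan coefficient
#'
#' \eqn{\langle j_1 m_1\, j_2 m_2 | J M \rangle} from the standard Racah
#' closed-form sum, evaluated with log-factorials. Returns 0 whenever the
#' triangle or projection selection rules fail. Arguments must be
#' (half-)integers; only integer angular momenta are needed by the rank-2
#' couplings in this package, but half-integers are supported.
#'
#' @param j1,m1,j2,m2,J,M angular momentum quantum numbers.
#' @return numeric coefficient.
#' @examples
#' clebsch_gordan(2, 0, 0, 0, 2, 0)  # 1
#' clebsch_gordan(2, 0, 2, 0, 0, 0)  # 1/sqrt(5)
#' @export
clebsch_gordan <- function(j1, m1, j2, m2, J, M) {
  args <- c(j1, m1, j2, m2, J, M)
  if (any(!is.finite(args)) || any(abs(args * 2 - round(args * 2)) > 1e-9))
    stop("invalid argument: quantum numbers must be (half-)integers", call. = FALSE)
  if (any(abs(c(2 * j1, 2 * j2, 2 * J) - round(c(2 * j1, 2 * j2, 2 * J))) > 0) ||
      j1 < 0 || j2 < 0 || J < 0)
    stop("invalid argument: j values must be nonnegative", call. = FALSE)
  # projection and triangle rules
  if (abs(m1) > j1 || abs(m2) > j2 || abs(M) > J) return(0)
  if (abs(m1 + m2 - M) > 1e-9) return(0)
  if (J < abs(j1 - j2) || J > j1 + j2) return(0)
  if (abs((j1 + j2 + J) - round(j1 + j2 + J)) > 1e-9) return(0)
  lf <- function(x) lgamma(x + 1)
  pref <- 0.5 * (log(2 * J + 1) +
                 lf(j1 + j2 - J) + lf(j1 - j2 + J) + lf(-j1 + j2 + J) -
                 lf(j1 + j2 + J + 1) +
                 lf(J + M) + lf(J - M) +
                 lf(j1 - m1) + lf(j1 + m1) + lf(j2 - m2) + lf(j2 + m2))
  kmin <- max(0, j2 - J - m1, j1 - J + m2)
  kmax <- min(j1 + j2 - J, j1 - m1, j2 + m2)
  if (kmax < kmin) return(0)
  total <- 0
  for (k in seq(kmin, kmax)) {
    lterm <- lf(k) + lf(j1 + j2 - J - k) + lf(j1 - m1 - k) +
      lf(j2 + m2 - k) + lf(J - j2 + m1 + k) + lf(J - j1 - m2 + k)
    total <- total + (-1)^k * exp(pref - lterm)
  }
  total
}
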