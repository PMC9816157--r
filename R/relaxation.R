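#' Quadrupolar coupling constant from the EFG variance
#'
#' \eqn{C_Q^2 = \frac{2}{3}\left(\frac{eQ}{\hbar}\right)^2 \langle V^2\rangle}
#' with the variance in SI units (V^2 m^-4); the positive root is returned
#' in rad/s.
#'
#' @param variance_si total EFG variance (V^2 m^-4).
#' @param Q nuclear quadrupole moment (m^2), default 23Na.
#' @return C_Q in rad/s.
#' @export
#' @examples
#' qcc(0)  # 0
qcc <- function(variance_si, Q = physical_constants$Q_23Na) {
  if (variance_si < 0) stop("variance must be non-negative")
  pc <- physical_constants
  sqrt(2 / 3 * (pc$e * Q / pc$hbar)^2 * variance_si)
}

#' Quadrupolar spin-lattice relaxation rate in extreme narrowing
#'
#' \deqn{\frac{1}{T_1} = \frac{2I+3}{20 I^2 (2I-1)}
#'   \left(\frac{eQ}{\hbar}\right)^2 \langle V^2\rangle \tau_c}
#' For \eqn{I = 3/2} the rate is identically \eqn{C_Q^2 \tau_c / 10}, which
#' is reported alongside. Valid only in the extreme-narrowing regime, where
#' longitudinal and transverse rates coincide; pass `larmor_hz` to have the
#' narrowing product evaluated and attached.
#'
#' @param variance_si total EFG variance (V^2 m^-4), electron-cloud
#'   enhancement already applied (see [predict_total_variance]).
#' @param tau_c effective correlation time (seconds).
#' @param I nuclear spin, one of 1, 3/2, 5/2, 7/2, 9/2.
#' @param Q nuclear quadrupole moment (m^2), default 23Na.
#' @param larmor_hz optional Larmor frequency (Hz) for the narrowing check.
#' @param variance_se optional SE of the variance, propagated linearly.
#' @return object of class `relaxation_result`: `rate` (1/T1, s^-1),
#'   `rate_se`, `C_Q` (rad/s), `tau_c`, `variance_si`, `prefactor`,
#'   `rate_qcc_form` (C_Q^2 tau_c / 10, I = 3/2 only), `narrowing`.
#' @export
#' @examples
#' # C_Q = 20e6 rad/s and tau_c = 0.5 ps give 20 Hz
#' v <- (20e6)^2 / (2 / 3 * (physical_constants$e * physical_constants$Q_23Na /
#'   physical_constants$hbar)^2)
#' quadrupolar_rate(v, 0.5e-12)$rate
quadrupolar_rate <- function(variance_si, tau_c, I = 3 / 2,
                             Q = physical_constants$Q_23Na,
                             larmor_hz = NULL, variance_se = 0) {
  if (!I %in% c(1, 3 / 2, 5 / 2, 7 / 2, 9 / 2))
    stop("I must be an integer or half-integer spin > 1/2")
  if (variance_si < 0 || tau_c < 0)
    stop("variance and tau_c must be non-negative")
  pc <- physical_constants
  prefactor <- (2 * I + 3) / (20 * I^2 * (2 * I - 1))
  coupling <- (pc$e * Q / pc$hbar)^2
  rate <- prefactor * coupling * variance_si * tau_c
  cq <- qcc(variance_si, Q)
  narrowing <- if (!is.null(larmor_hz))
    narrowing_check(tau_c, larmor_hz) else NULL
  structure(list(
    rate = rate,
    rate_se = prefactor * coupling * variance_se * tau_c,
    C_Q = cq,
    tau_c = tau_c,
    variance_si = variance_si,
    I = I, Q = Q,
    prefactor = prefactor,
    rate_qcc_form = if (I == 3 / 2) cq^2 * tau_c / 10 else NA_real_,
    narrowing = narrowing
  ), class = "relaxation_result")
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat(sprintf("1/T1 = %.6g s^-1  (C_Q = %.4g rad/s, tau_c = %.4g s, I = %g)\n",
              x$rate, x$C_Q, x$tau_c, x$I))
  if (!is.null(x$narrowing))
    cat(sprintf("  narrowing product (omega0 = 2 pi f): %.3g -> %s\n",
                x$narrowing$product_angular,
                if (x$narrowing$pass) "extreme narrowing holds" else "FAILS"))
  invisible(x)
}

#' Extreme-narrowing validity check
#'
#' The extreme-narrowing regime requires \eqn{\omega_0 \tau_c \ll 1}. The
#' product is reported under both the angular convention
#' \eqn{\omega_0 = 2\pi f} and the plain-frequency convention
#' \eqn{\omega_0 = f} (both appear in practice); the pass criterion uses the
#' angular product with threshold 0.01, and a product at the threshold
#' passes with a warning.
#'
#' @param tau_c correlation time (seconds).
#' @param larmor_hz Larmor frequency f (Hz).
#' @param threshold pass threshold on the angular product.
#' @return list `product_angular`, `product_plain`, `pass`, `threshold`.
#' @export
#' @examples
#' narrowing_check(0.5e-12, 132.3e6)$pass  # TRUE
narrowing_check <- function(tau_c, larmor_hz, threshold = 0.01) {
  if (tau_c < 0 || larmor_hz <= 0) stop("inputs must be positive")
  pa <- 2 * pi * larmor_hz * tau_c
  pp <- larmor_hz * tau_c
  pass <- pa <= threshold
  if (pass && pa >= 0.99 * threshold)
    warning("narrowing product at the validity boundary")
  list(product_angular = pa, product_plain = pp, pass = pass,
       threshold = threshold)
}
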