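#' Construct a stress tensor time series
#'
#' @param stress array (n_frames x 3 x 3) of instantaneous stress tensors,
#'   in Pascal.
#' @param dt sampling interval (fs).
#' @param volume box volume (m^3).
#' @param temperature temperature (K).
#' @return object of class `stress_series`.
#' @export
stress_series <- function(stress, dt, volume, temperature) {
  if (length(dim(stress)) != 3L || any(dim(stress)[2:3] != 3L))
    stop("stress must be an n x 3 x 3 array")
  if (volume <= 0 || temperature <= 0 || dt <= 0)
    stop("dt, volume and temperature must be positive")
  structure(list(stress = stress, dt = dt, volume = volume,
                 temperature = temperature),
            class = "stress_series")
}

#' Stress autocorrelation function for Green-Kubo viscosity
#'
#' Symmetrizes each frame, removes the isotropic (pressure) part,
#' \eqn{P_{\alpha\beta} = \tfrac12(\sigma_{\alpha\beta}+\sigma_{\beta\alpha})
#' - \tfrac13\delta_{\alpha\beta}\sum_\gamma \sigma_{\gamma\gamma}},
#' and returns the multi-origin ACF
#' \eqn{C_{stress}(t) = \tfrac1{10}\sum_{\alpha\beta}
#' \langle P_{\alpha\beta}(t) P_{\alpha\beta}(0)\rangle}.
#' Isotropic offsets and antisymmetric components have no effect.
#'
#' @param series a [stress_series].
#' @param max_lag maximum lag (fs).
#' @param estimator passed to [tensor_acf].
#' @return a `tensor_acf` (values in Pa^2) carrying `volume` and
#'   `temperature` attributes.
#' @export
stress_acf <- function(series, max_lag = NULL,
                       estimator = c("fft", "direct")) {
  stopifnot(inherits(series, "stress_series"))
  s <- series$stress
  n <- dim(s)[1]
  if (n < 2L) stop("need at least 2 frames")
  comps <- matrix(0, n, 6L, dimnames = list(NULL, tensor_comp_names))
  tr3 <- (s[, 1, 1] + s[, 2, 2] + s[, 3, 3]) / 3
  comps[, "xx"] <- s[, 1, 1] - tr3
  comps[, "yy"] <- s[, 2, 2] - tr3
  comps[, "zz"] <- s[, 3, 3] - tr3
  comps[, "xy"] <- (s[, 1, 2] + s[, 2, 1]) / 2
  comps[, "xz"] <- (s[, 1, 3] + s[, 3, 1]) / 2
  comps[, "yz"] <- (s[, 2, 3] + s[, 3, 2]) / 2
  acf <- tensor_acf(comps, max_lag = max_lag, estimator = estimator,
                    prefactor = 1 / 10, dt = series$dt)
  acf$volume <- series$volume
  acf$temperature <- series$temperature
  acf
}

#' Green-Kubo shear viscosity from the stress ACF
#'
#' \eqn{\eta = \frac{V}{k_B T}\int_0^\infty C_{stress}(t)\,dt}. The
#' running integral and the plateau-detection cutoff policy are shared with
#' [correlation_time]; a non-plateauing integral is flagged, never silent.
#'
#' @param acf a `tensor_acf` from [stress_acf] (Pa^2), or any tensor ACF
#'   with explicit `volume`/`temperature` arguments.
#' @param volume box volume (m^3); defaults to the ACF attribute.
#' @param temperature temperature (K); defaults to the ACF attribute.
#' @param cutoff_policy as in [correlation_time].
#' @return list `eta` (Pa s), `cutoff_fs`, `plateau_found`, `running`
#'   (data frame: lag_fs, eta_running).
#' @export
green_kubo_viscosity <- function(acf, volume = acf$volume,
                                 temperature = acf$temperature,
                                 cutoff_policy = list(method = "plateau")) {
  stopifnot(inherits(acf, "tensor_acf"))
  if (is.null(volume) || is.null(temperature))
    stop("volume and temperature are required")
  if (acf$c0 == 0)
    return(list(eta = 0, cutoff_fs = max(acf$lag_fs), plateau_found = NA,
                running = data.frame(lag_fs = acf$lag_fs,
                                     eta_running = 0 * acf$lag_fs)))
  ct <- correlation_time(acf, cutoff_policy)
  scale <- volume / (physical_constants$k_B * temperature) * 1e-15  # fs -> s
  eta_running <- ct$running$integral_fs * acf$c0 * scale
  i_cut <- max(which(ct$running$lag_fs <= ct$cutoff))
  if (identical(ct$plateau_found, FALSE) && !isTRUE(ct$fallback_used))
    warning("stress ACF running integral did not plateau; ",
            "viscosity estimate flagged")
  list(eta = ct$tau_c * acf$c0 * scale, cutoff_fs = ct$cutoff,
       plateau_found = ct$plateau_found,
       running = data.frame(lag_fs = ct$running$lag_fs,
                            eta_running = eta_running))
}

#' Diffusion coefficient from the mean-squared displacement
#'
#' \eqn{D = \lim_{t\to\infty} \mathrm{MSD}(t) / 6t} estimated as the
#' least-squares slope of the multi-origin MSD over a fit window in the
#' diffusive regime. The local log-log slope over the window must be within
#' 1 +- 0.1, otherwise the data are flagged as non-diffusive (ballistic or
#' caged) and an error is raised unless `check = FALSE`.
#'
#' @param traj unwrapped positions: array (n_frames x 3 x n_walkers) in
#'   Angstrom, or a matrix for a single walker.
#' @param dt sampling interval (fs).
#' @param fit_window fractions of the maximum lag used for the linear fit,
#'   default c(0.1, 0.5).
#' @param check enforce the diffusive-regime check (default TRUE).
#' @return object of class `diffusion_result`: `D` (m^2/s), `D_angstrom_fs`
#'   (native units), `r_squared`, `loglog_slope`, `fit_window_fs`, `msd`
#'   (data frame lag_fs, msd_A2).
#' @export
msd_diffusion <- function(traj, dt, fit_window = c(0.1, 0.5), check = TRUE) {
  if (length(dim(traj)) == 2L) traj <- array(traj, c(dim(traj), 1L))
  n <- dim(traj)[1]
  nw <- dim(traj)[3]
  if (n < 10L) stop("trajectory too short for an MSD fit")
  n_lag <- n - 1L
  msd <- numeric(n_lag + 1L)
  for (w in seq_len(nw))
    for (d in 1:3)
      msd <- msd + msd_fft(traj[, d, w])
  msd <- msd / nw
  lag_fs <- (0:n_lag) * dt
  lo <- fit_window[1] * lag_fs[n_lag + 1L]
  hi <- fit_window[2] * lag_fs[n_lag + 1L]
  sel <- lag_fs >= lo & lag_fs <= hi & lag_fs > 0
  if (sum(sel) < 5L) stop("fit window contains fewer than 5 lags")
  msd_scale <- mean(traj^2) + 1
  if (all(abs(msd[sel]) < 1e-9 * msd_scale)) {   # static (FFT roundoff)
    return(structure(list(D = 0, D_angstrom_fs = 0, r_squared = NA_real_,
                          loglog_slope = NA_real_,
                          fit_window_fs = c(lo, hi),
                          msd = data.frame(lag_fs = lag_fs, msd_A2 = msd)),
                     class = "diffusion_result"))
  }
  ll <- stats::lm(log(msd[sel]) ~ log(lag_fs[sel]))
  slope_ll <- unname(stats::coef(ll)[2])
  if (check && abs(slope_ll - 1) > 0.1)
    stop(sprintf(paste0("MSD not in the diffusive regime over the fit ",
                        "window (log-log slope %.3f); adjust the window ",
                        "or pass check = FALSE"), slope_ll))
  fit <- stats::lm(msd[sel] ~ lag_fs[sel])
  d_af <- unname(stats::coef(fit)[2]) / 6          # Angstrom^2 / fs
  structure(list(D = d_af * 1e-5,                  # -> m^2/s
                 D_angstrom_fs = d_af,
                 r_squared = summary(fit)$r.squared,
                 loglog_slope = slope_ll,
                 fit_window_fs = c(lo, hi),
                 msd = data.frame(lag_fs = lag_fs, msd_A2 = msd)),
            class = "diffusion_result")
}

# multi-origin MSD of one coordinate via the FFT autocorrelation identity
msd_fft <- function(x) {
  n <- length(x)
  raw <- acf_raw_fft(x, n - 1L)          # sum_t x_t x_{t+l}
  x2 <- x * x
  # S1(l) = sum_t (x_t^2 + x_{t+l}^2) over valid origins, via cumsums
  cs <- cumsum(x2)
  tot <- cs[n]
  s1 <- vapply(0:(n - 1L), function(l) {
    if (l == 0) 2 * tot else (cs[n - l]) + (tot - cs[l])
  }, numeric(1))
  (s1 - 2 * raw) / (n - 0:(n - 1L))
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("D = %.6g m^2/s (R^2 = %.4f, log-log slope %.3f)\n",
              x$D, x$r_squared, x$loglog_slope))
  invisible(x)
}

#' Finite-size (Yeh-Hummer) correction of a diffusion coefficient
#'
#' \eqn{D_\infty = D + k_B T \xi / 6\pi\eta L} with the cubic-lattice
#' constant \eqn{\xi \approx 2.837297} (see [xi_cubic]).
#'
#' @param D box diffusion coefficient (m^2/s).
#' @param eta shear viscosity (Pa s).
#' @param temperature temperature (K).
#' @param L cubic box edge (m).
#' @param xi lattice constant; defaults to the computed value.
#' @return list `D_inf`, `correction`, `fraction` (= correction / D), `xi`.
#' @export
yeh_hummer_correct <- function(D, eta, temperature, L, xi = xi_cubic()) {
  if (eta <= 0 || temperature <= 0 || L <= 0)
    stop("eta, temperature and L must be positive")
  xi <- as.numeric(xi)
  corr <- physical_constants$k_B * temperature * xi / (6 * pi * eta * L)
  list(D_inf = D + corr, correction = corr,
       fraction = if (D > 0) corr / D else NA_real_, xi = xi)
}

#' Cubic-lattice self-interaction constant for finite-size diffusion
#'
#' The dimensionless Wigner constant of a point charge in a cubic periodic
#' cell with uniform neutralizing background, computed from the Ewald-split
#' lattice sum in a unit cube:
#' \deqn{-\xi = \sum_{n\ne 0}\frac{\mathrm{erfc}(\alpha|n|)}{|n|}
#'  + \sum_{k\ne 0}\frac{4\pi}{k^2} e^{-k^2/4\alpha^2}
#'  - \frac{2\alpha}{\sqrt\pi} - \frac{\pi}{\alpha^2}}
#' with \eqn{k = 2\pi m}. The value is invariant to the splitting parameter
#' within the tolerance; shell counts are driven by the tolerance.
#'
#' @param tol absolute tolerance (default 1e-8).
#' @param alpha Ewald splitting parameter (default 2, near-optimal for the
#'   unit cube).
#' @param max_shell cap on the number of real/reciprocal shells; reaching
#'   the cap without convergence raises a convergence flag via warning.
#' @return xi (about 2.837297), with attribute `"converged"`.
#' @export
#' @examples
#' xi_cubic()
xi_cubic <- function(tol = 1e-8, alpha = 2, max_shell = 50L) {
  f <- sqrt(-log(tol)) + 1
  n_real <- min(max_shell, max(2L, ceiling(f / alpha)))
  n_k <- min(max_shell, max(2L, ceiling(alpha * f / pi)))
  g <- seq.int(-n_real, n_real)
  nn <- as.matrix(expand.grid(x = g, y = g, z = g))
  nn <- nn[rowSums(nn != 0) > 0L, , drop = FALSE]
  r <- sqrt(rowSums(nn * nn))
  real_sum <- sum(pracma::erfc(alpha * r) / r)
  gk <- seq.int(-n_k, n_k)
  mm <- as.matrix(expand.grid(x = gk, y = gk, z = gk))
  mm <- mm[rowSums(mm != 0) > 0L, , drop = FALSE]
  k2 <- rowSums(mm * mm) * (2 * pi)^2
  recip_sum <- sum(4 * pi * exp(-k2 / (4 * alpha^2)) / k2)
  v <- real_sum + recip_sum - 2 * alpha / sqrt(pi) - pi / alpha^2
  # convergence: residual of the outermost real shell must be below tol
  outer_term <- pracma::erfc(alpha * n_real) / n_real
  converged <- outer_term < tol && exp(-(pi * n_k / alpha)^2) < tol
  if (!converged)
    warning("xi lattice sum not converged at the shell cap")
  structure(-v, converged = converged)
}

#' Hydrodynamic (Stokes) radius from diffusion and viscosity
#'
#' Translational Stokes-Einstein relation \eqn{r_0 = k_B T / 6\pi\eta D}.
#'
#' @param D diffusion coefficient (m^2/s).
#' @param eta viscosity (Pa s).
#' @param temperature temperature (K).
#' @return r0 in meters.
#' @export
stokes_radius <- function(D, eta, temperature) {
  if (D <= 0 || eta <= 0 || temperature <= 0)
    stop("all inputs must be positive")
  physical_constants$k_B * temperature / (6 * pi * eta * D)
}

#' Stokes-Einstein-Debye rotational correlation time
#'
#' \eqn{\tau_{SED} = 4\pi\eta r_0^3 / 3 k_B T} for a sphere of radius r0
#' rotating in a continuum of viscosity eta.
#'
#' @param eta viscosity (Pa s).
#' @param r0 hydrodynamic radius (m).
#' @param temperature temperature (K).
#' @return tau_SED in seconds.
#' @export
sed_time <- function(eta, r0, temperature) {
  if (eta <= 0 || r0 <= 0 || temperature <= 0)
    stop("all inputs must be positive")
  4 * pi * eta * r0^3 / (3 * physical_constants$k_B * temperature)
}

#' Effective hydrodynamic radius from correlation times across state points
#'
#' Fits \eqn{\tau_c = 4\pi [r_0^{eff}]^3 \eta / 3 k_B T + \tau_0^{eff}}
#' by linear regression of the correlation times on \eqn{\eta / k_B T}; the
#' slope gives the effective radius, the intercept is reported as
#' \eqn{\tau_0^{eff}}.
#'
#' @param tau_c correlation times (seconds), one per state point (>= 3).
#' @param eta_over_kbt values of eta / k_B T (s / m^3).
#' @return list `r0_eff` (m, NA with a warning for a negative slope),
#'   `tau0_eff` (s), `slope`, `slope_se`, `intercept_se`, `r_squared`.
#' @export
effective_sed_fit <- function(tau_c, eta_over_kbt) {
  if (length(tau_c) < 3L) stop("need at least 3 state points")
  if (length(tau_c) != length(eta_over_kbt))
    stop("inputs must have equal length")
  fit <- stats::lm(tau_c ~ eta_over_kbt)
  co <- stats::coef(fit)
  # suppressed: lm warns on exactly collinear (noise-free) inputs
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(co[2])
  r0 <- if (slope < 0) {
    warning("negative slope: no real effective radius")
    NA_real_
  } else (3 * slope / (4 * pi))^(1 / 3)
  list(r0_eff = r0, tau0_eff = unname(co[1]), slope = slope,
       slope_se = sm[2, 2], intercept_se = sm[1, 2],
       r_squared = suppressWarnings(summary(fit))$r.squared)
}

#' Water dipole reorientation time
#'
#' \eqn{\tau_{dip} = \int_0^\infty \langle P_1[u(t)\cdot u(0)]\rangle dt}
#' with \eqn{P_1(x) = x}, the first-rank orientational correlation of the
#' HOH-bisector unit vectors, averaged over molecules and time origins.
#'
#' @param orient array (n_frames x 3 x n_molecules) of unit vectors.
#' @param dt sampling interval (fs).
#' @param cutoff_policy as in [correlation_time].
#' @return list `tau_dip_fs`, `tau_dip_s`, `acf` (`tensor_acf` of the P1
#'   correlation), `decayed` (FALSE with a warning for frozen orientations).
#' @export
dipole_reorientation_time <- function(orient, dt,
                                      cutoff_policy =
                                        list(method = "plateau")) {
  if (length(dim(orient)) == 2L) orient <- array(orient, c(dim(orient), 1L))
  norms <- sqrt(orient[, 1, , drop = FALSE]^2 + orient[, 2, , drop = FALSE]^2 +
                  orient[, 3, , drop = FALSE]^2)
  if (max(abs(norms - 1)) > 1e-8)
    stop("orientation vectors must be unit length")
  acf <- tensor_acf(orient, estimator = "fft",
                    comp_weights = c(1, 1, 1), dt = dt)
  cn <- acf$value / acf$c0
  decayed <- cn[length(cn)] < 0.5
  if (!decayed)
    warning("orientational ACF has not decayed; tau_dip unreliable ",
            "(frozen or slow orientations)")
  ct <- if (decayed) correlation_time(acf, cutoff_policy)
        else suppressWarnings(correlation_time(acf, cutoff_policy))
  list(tau_dip_fs = ct$tau_c, tau_dip_s = ct$tau_c * 1e-15, acf = acf,
       decayed = decayed)
}

#' Structural relaxation time from the stress ACF tail
#'
#' Fits a stretched exponential \eqn{\sim e^{-(t/\tau_K)^{\beta_K}}} to the
#' long-time tail of the stress ACF, past the short-time elastic and
#' vibrational part, and reports the mean structural relaxation time
#' \eqn{\tau_{struct} = \tau_K \beta_K^{-1} \Gamma(\beta_K^{-1})}.
#' The default tail window starts at the first local minimum of |C(t)|
#' after the initial decay (stress ACFs oscillate at short times).
#'
#' @param acf a `tensor_acf` of the stress (from [stress_acf]).
#' @param tail_window optional `c(tmin, tmax)` (fs) overriding the default.
#' @return object of class `structural_relax_result`: `tau_K_fs`,
#'   `beta_K`, `tau_struct_fs`, `fit` (`acf_fit`), `window_fs`.
#' @export
structural_relaxation_time <- function(acf, tail_window = NULL) {
  stopifnot(inherits(acf, "tensor_acf"))
  t <- acf$lag_fs
  if (is.null(tail_window)) {
    a <- abs(acf$value / acf$c0)
    # first local minimum marks the end of the oscillatory elastic part;
    # for monotone ACFs fall back to the half-decay lag so the window
    # still spans the decay rather than pure estimator noise
    i0 <- NA_integer_
    for (i in 2:(length(a) - 1L))
      if (a[i] <= a[i - 1] && a[i] < a[i + 1]) { i0 <- i; break }
    i_half <- which(a < 0.5)[1]
    i0 <- min(i0, i_half, na.rm = TRUE)
    if (!is.finite(i0)) i0 <- max(2L, floor(length(a) * 0.05))
    tail_window <- c(t[i0], max(t))
  }
  fit <- fit_acf(acf, "stretched", window = tail_window)
  if (!isTRUE(fit$converged) || is.null(fit$par))
    warning("stretched tail fit did not converge; flagged result")
  tau_k <- fit$par$tau_s %||% NA_real_
  beta_k <- fit$par$beta %||% NA_real_
  structure(list(tau_K_fs = tau_k, beta_K = beta_k,
                 tau_struct_fs = if (is.na(tau_k)) NA_real_
                                 else stretched_mean_time(tau_k, beta_k),
                 fit = fit, window_fs = tail_window),
            class = "structural_relax_result")
}

#' @export
print.structural_relax_result <- function(x, ...) {
  cat(sprintf("tau_K = %.4g fs, beta_K = %.3f, tau_struct = %.4g fs\n",
              x$tau_K_fs, x$beta_K, x$tau_struct_fs))
  invisible(x)
}
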