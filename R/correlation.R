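#' Multi-origin autocorrelation of a tensor time series
#'
#' Computes \eqn{C(t) = \langle V(0):V(t)\rangle} as the multi-origin average
#' of the Frobenius contraction, summed over the 6 independent components
#' with off-diagonal double counting, averaged over probes. The EFG (and
#' traceless stress) processes are zero-mean by symmetry, so no mean is
#' subtracted. The `fft` and `direct` estimators implement the identical
#' statistic and agree to machine precision.
#'
#' @param series an `efg_series`, or a plain numeric matrix (frames x
#'   components) with `comp_weights` supplied.
#' @param max_lag maximum lag in fs (default: half the series span).
#' @param estimator `"fft"` (Wiener-Khinchin, default) or `"direct"`.
#' @param comp_weights per-component weights in the contraction; defaults to
#'   the symmetric-tensor weights (1,1,1,2,2,2) for 6-component input.
#' @param prefactor overall scale applied to the ACF (1 for EFG input; the
#'   stress ACF uses 1/10 via [stress_acf]).
#' @param dt sampling interval (fs) when `series` is a plain matrix.
#' @return object of class `tensor_acf`: `lag_fs`, `value`, `stderr`
#'   (between-probe/run standard error, NA for one probe), `n_origins`,
#'   `c0`, `dt`.
#' @export
tensor_acf <- function(series, max_lag = NULL, estimator = c("fft", "direct"),
                       comp_weights = NULL, prefactor = 1, dt = NULL) {
  estimator <- match.arg(estimator)
  if (inherits(series, "efg_series")) {
    comps <- series$comps
    dt <- series$dt
  } else {
    comps <- series
    if (length(dim(comps)) == 2L) comps <- array(comps, c(dim(comps), 1L))
    if (is.null(dt)) stop("dt must be given for plain matrix input")
  }
  n <- dim(comps)[1]
  if (n < 2L) stop("need at least 2 frames for an autocorrelation")
  n_comp <- dim(comps)[2]
  n_probe <- dim(comps)[3]
  if (is.null(comp_weights))
    comp_weights <- if (n_comp == 6L) tensor_comp_weights else rep(1, n_comp)
  if (is.null(max_lag)) max_lag <- (n - 1) %/% 2 * dt
  n_lag <- min(n - 1L, floor(max_lag / dt + 1e-9))
  lags <- 0:n_lag

  per_probe <- matrix(0, n_lag + 1L, n_probe)
  for (j in seq_len(n_probe)) {
    acc <- numeric(n_lag + 1L)
    for (k in seq_len(n_comp)) {
      x <- comps[, k, j]
      raw <- if (estimator == "fft") acf_raw_fft(x, n_lag)
             else acf_raw_direct(x, n_lag)
      acc <- acc + comp_weights[k] * raw
    }
    per_probe[, j] <- acc / (n - lags)   # multi-origin normalization
  }
  value <- rowMeans(per_probe) * prefactor
  stderr <- if (n_probe > 1L)
    apply(per_probe, 1L, stats::sd) / sqrt(n_probe) * prefactor
  else rep(NA_real_, n_lag + 1L)
  structure(list(lag_fs = lags * dt, value = value, stderr = stderr,
                 n_origins = n - lags, c0 = value[1], dt = dt,
                 n_probes = n_probe),
            class = "tensor_acf")
}

# unnormalized lagged products sum_t x_t x_{t+l}, l = 0..n_lag
acf_raw_fft <- function(x, n_lag) {
  n <- length(x)
  m <- stats::nextn(2L * n, 2L)
  xp <- c(x, numeric(m - n))
  ft <- stats::fft(xp)
  full <- Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / m
  full[seq_len(n_lag + 1L)]
}

acf_raw_direct <- function(x, n_lag) {
  n <- length(x)
  vapply(0:n_lag, function(l) sum(x[seq_len(n - l)] * x[seq_len(n - l) + l]),
         numeric(1))
}

#' @export
print.tensor_acf <- function(x, ...) {
  cat(sprintf("tensor_acf: %d lags, dt = %g fs, C(0) = %.6g\n",
              length(x$lag_fs), x$dt, x$c0))
  invisible(x)
}

#' Effective correlation time from an autocorrelation function
#'
#' \eqn{\tau_c = C(0)^{-1}\int_0^{t_{cut}} C(t)\,dt} by trapezoidal
#' quadrature, with an optional analytic tail correction beyond the cutoff
#' from a fitted decay model. The default cutoff policy integrates the
#' running integral until its slope stays below a small fraction of its peak
#' slope over a trailing window ("plateau detection"); if no plateau is
#' found the full lag range is used and flagged.
#'
#' @param acf a `tensor_acf`.
#' @param cutoff_policy list with `method` one of `"plateau"`, `"full"`,
#'   `"fixed"`; for `"fixed"` give `cutoff` (fs); for `"plateau"`,
#'   `slope_frac` (default 1e-3) and `window` (fs, default 10% of the lag
#'   range).
#' @param tail_fit optional `acf_fit` used to extend the integral
#'   analytically from the cutoff to infinity.
#' @return object of class `correlation_time`: `tau_c` (fs), `cutoff`
#'   (fs), `method`, `tail_correction` (fs), `plateau_found`, `running`
#'   (data frame of the running integral, fs).
#' @export
correlation_time <- function(acf, cutoff_policy = list(method = "plateau"),
                             tail_fit = NULL) {
  stopifnot(inherits(acf, "tensor_acf"))
  if (acf$c0 <= 0) stop("C(0) must be positive")
  t <- acf$lag_fs
  cn <- acf$value / acf$c0
  running <- c(0, cumsum((cn[-1] + cn[-length(cn)]) / 2 * diff(t)))
  method <- cutoff_policy$method %||% "plateau"
  plateau_found <- NA
  fallback_used <- FALSE
  if (method == "fixed") {
    cutoff <- cutoff_policy$cutoff
    if (is.null(cutoff) || cutoff > max(t))
      stop("fixed cutoff policy needs a cutoff within the lag range")
    i_cut <- max(which(t <= cutoff))
  } else if (method == "full") {
    i_cut <- length(t)
    cutoff <- t[i_cut]
  } else if (method == "plateau") {
    slope_frac <- cutoff_policy$slope_frac %||% 1e-3
    window <- cutoff_policy$window %||% (0.1 * max(t))
    wi <- max(2L, ceiling(window / acf$dt))
    slopes <- abs(cn)          # |C_n| is the slope of the running integral
    peak <- max(slopes)
    below <- slopes < slope_frac * peak
    i_cut <- NA_integer_
    run <- 0L
    for (i in seq_along(below)) {
      run <- if (below[i]) run + 1L else 0L
      if (run >= wi) { i_cut <- i - wi + 1L; break }
    }
    plateau_found <- !is.na(i_cut)
    fallback_used <- FALSE
    if (!plateau_found) {
      fallback_used <- TRUE
      # estimator noise can keep |C| above the slope threshold forever;
      # fall back to a fixed multiple of the fitted slow relaxation time
      fallback_mult <- cutoff_policy$fallback_mult %||% 10
      # fit the slow tail only (past the fast initial decay) so that the
      # extrapolation is not biased by the fast mode
      i_slow <- which(cn < 0.2)
      fb_win <- if (length(i_slow) && length(t) - i_slow[1] >= 20L)
        c(t[i_slow[1]], max(t)) else range(t)
      fb <- tryCatch(fit_acf(acf, "stretched", window = fb_win),
                     error = function(e) NULL)
      if (!is.null(fb) && isTRUE(fb$converged) && !is.null(fb$par)) {
        t_slow <- stretched_mean_time(fb$par$tau_s, fb$par$beta)
        i_cut <- max(which(t <= min(fallback_mult * t_slow, max(t))))
        # extend past the cutoff with the fitted tail unless the caller
        # supplied an explicit tail model
        if (is.null(tail_fit)) tail_fit <- fb
      } else i_cut <- length(t)
    }
    cutoff <- t[i_cut]
  } else stop("unknown cutoff policy method")

  tail_corr <- 0
  if (!is.null(tail_fit)) tail_corr <- acf_fit_tail_integral(tail_fit, cutoff)
  if (identical(plateau_found, FALSE) && is.null(tail_fit) &&
      i_cut == length(t) && abs(cn[length(cn)]) > 0.01)
    warning("no plateau found and ACF not decayed at the last lag; ",
            "tau_c may be underestimated")
  structure(list(tau_c = running[i_cut] + tail_corr, cutoff = cutoff,
                 method = if (!is.null(tail_fit)) "fit-assisted"
                          else "direct-integral",
                 tail_correction = tail_corr, plateau_found = plateau_found,
                 fallback_used = fallback_used,
                 running = data.frame(lag_fs = t, integral_fs = running)),
            class = "correlation_time")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correlation_time <- function(x, ...) {
  cat(sprintf("tau_c = %.6g fs (%s, cutoff %.6g fs, tail %.3g fs)\n",
              x$tau_c, x$method, x$cutoff, x$tail_correction))
  invisible(x)
}

# analytic integral of a fitted (normalized) decay model beyond t0, in fs
acf_fit_tail_integral <- function(fit, t0) {
  p <- fit$par
  tail_exp <- function(a, tau) a * tau * exp(-t0 / tau)
  tail_str <- function(a, tau, beta) {
    # int_t0^inf e^(-(t/tau)^beta) dt = (tau/beta) * IncGamma(1/beta, (t0/tau)^beta)
    a * (tau / beta) * pracma::incgam((t0 / tau)^beta, 1 / beta)
  }
  switch(fit$model,
    fast_exp = tail_exp(p$a, p$tau_f),
    double_exp = tail_exp(p$a1, p$tau1) + tail_exp(p$a2, p$tau2),
    stretched = tail_str(p$a, p$tau_s, p$beta),
    fast_plus_stretched = tail_exp(p$a_f, p$tau_f) +
      tail_str(p$a_s, p$tau_s, p$beta),
    stop("unknown model tag"))
}

# mean relaxation time of a stretched exponential, tau * Gamma(1/beta) / beta
stretched_mean_time <- function(tau, beta) tau * gamma(1 / beta) / beta

#' Fit a decay model to a normalized autocorrelation function
#'
#' Nonlinear least squares (Levenberg-Marquardt) on \eqn{C(t)/C(0)} over a
#' lag window. Supported models: `fast_exp` \eqn{a e^{-t/\tau_f}};
#' `double_exp` \eqn{a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}}; `stretched`
#' \eqn{a e^{-(t/\tau_s)^\beta}}; `fast_plus_stretched`
#' \eqn{a_f e^{-t/\tau_f} + a_s e^{-(t/\tau_s)^\beta}}. Initialization uses
#' a deterministic multi-start grid (3 starts per decade of time constant);
#' the best converged fit by residual norm is returned.
#'
#' @param acf a `tensor_acf`.
#' @param model model tag (see Description).
#' @param window lag window `c(tmin, tmax)` in fs; default the full range.
#' @param beta_fixed optionally pin the stretching exponent.
#' @return object of class `acf_fit`: `model`, `par` (named list), `se`
#'   (from the Jacobian), `window`, `resid_norm`, `converged`, `n_points`.
#'   Non-convergence is flagged, never silent.
#' @export
fit_acf <- function(acf, model = c("fast_exp", "double_exp", "stretched",
                                   "fast_plus_stretched"),
                    window = NULL, beta_fixed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(acf, "tensor_acf"))
  t <- acf$lag_fs
  y <- acf$value / acf$c0
  if (is.null(window)) window <- range(t)
  sel <- t >= window[1] & t <= window[2]
  tt <- t[sel]; yy <- y[sel]
  n_par <- switch(model, fast_exp = 2L, double_exp = 4L, stretched = 3L,
                  fast_plus_stretched = 5L)
  if (!is.null(beta_fixed)) n_par <- n_par - 1L
  if (sum(sel) < 5L * n_par)
    stop("need at least 5 points per free parameter in the fit window")

  # crude time scale from the 1/e crossing for start grids
  t_e <- if (any(yy < exp(-1) * yy[1])) tt[which(yy < exp(-1) * yy[1])[1]]
         else max(tt) / 2
  t_e <- max(t_e, acf$dt)
  grid <- t_e * 10^seq(-1, 1, by = 1 / 3)   # 3 starts per decade

  fits <- list()
  mk_fit <- function(formula, start, lower, upper) {
    tryCatch({
      f <- minpack.lm::nlsLM(formula, data = data.frame(tt = tt, yy = yy),
                             start = start, lower = lower, upper = upper,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
      list(par = as.list(stats::coef(f)),
           se = tryCatch(sqrt(diag(stats::vcov(f))),
                         error = function(e) rep(NA_real_,
                                                 length(stats::coef(f)))),
           resid_norm = sqrt(sum(stats::resid(f)^2)),
           converged = f$convInfo$isConv %||% TRUE)
    }, error = function(e) NULL)
  }

  for (tau0 in grid) {
    f <- switch(model,
      fast_exp = mk_fit(yy ~ a * exp(-tt / tau_f),
                        list(a = yy[1], tau_f = tau0),
                        c(a = 0, tau_f = acf$dt / 100),
                        c(a = 2, tau_f = Inf)),
      double_exp = mk_fit(yy ~ a1 * exp(-tt / tau1) + a2 * exp(-tt / tau2),
                          list(a1 = 0.6 * yy[1], tau1 = tau0 / 3,
                               a2 = 0.4 * yy[1], tau2 = tau0 * 3),
                          c(a1 = 0, tau1 = acf$dt / 100, a2 = 0,
                            tau2 = acf$dt / 100),
                          c(a1 = 2, tau1 = Inf, a2 = 2, tau2 = Inf)),
      stretched = if (is.null(beta_fixed))
        mk_fit(yy ~ a * exp(-(tt / tau_s)^beta),
               list(a = yy[1], tau_s = tau0, beta = 0.7),
               c(a = 0, tau_s = acf$dt / 100, beta = 0.05),
               c(a = 2, tau_s = Inf, beta = 1))
      else
        mk_fit(stats::as.formula(
                 sprintf("yy ~ a * exp(-(tt / tau_s)^%.12g)", beta_fixed)),
               list(a = yy[1], tau_s = tau0),
               c(a = 0, tau_s = acf$dt / 100), c(a = 2, tau_s = Inf)),
      fast_plus_stretched = mk_fit(
        yy ~ a_f * exp(-tt / tau_f) + a_s * exp(-(tt / tau_s)^beta),
        list(a_f = 0.7 * yy[1], tau_f = tau0 / 10,
             a_s = 0.3 * yy[1], tau_s = tau0 * 3, beta = 0.7),
        c(a_f = 0, tau_f = acf$dt / 100, a_s = 0, tau_s = acf$dt / 100,
          beta = 0.05),
        c(a_f = 2, tau_f = Inf, a_s = 2, tau_s = Inf, beta = 1)))
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) {
    warning("acf fit did not converge from any start; flagged result")
    return(structure(list(model = model, par = NULL, se = NULL,
                          window = window, resid_norm = NA_real_,
                          converged = FALSE, n_points = sum(sel)),
                     class = "acf_fit"))
  }
  best <- fits[[which.min(vapply(fits, function(f) f$resid_norm,
                                 numeric(1)))]]
  par <- best$par
  if (!is.null(beta_fixed) && model == "stretched") par$beta <- beta_fixed
  structure(list(model = model, par = par, se = best$se, window = window,
                 resid_norm = best$resid_norm, converged = best$converged,
                 n_points = sum(sel)),
            class = "acf_fit")
}

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf("acf_fit [%s]%s: ", x$model,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  if (!is.null(x$par))
    cat(paste(names(x$par), signif(unlist(x$par), 5), sep = " = ",
              collapse = ", "))
  cat(sprintf("\n  window [%g, %g] fs, resid %.3g, %d points\n",
              x$window[1], x$window[2], x$resid_norm, x$n_points))
  invisible(x)
}

#' Fraction of the correlation time carried by the slow relaxation mode
#'
#' For a composite fit, each mode contributes amplitude times mean time to
#' the ACF integral; the slow-mode fraction is its share of the total. The
#' mean time of a stretched component is \eqn{\tau_K \Gamma(1/\beta)/\beta}.
#'
#' @param fit an `acf_fit` of model `fast_plus_stretched` or `double_exp`.
#' @return fraction in \[0, 1\].
#' @export
slow_mode_fraction <- function(fit) {
  stopifnot(inherits(fit, "acf_fit"))
  if (is.null(fit$par)) stop("cannot decompose a non-converged fit")
  p <- fit$par
  if (fit$model == "fast_plus_stretched") {
    fast <- p$a_f * p$tau_f
    slow <- p$a_s * stretched_mean_time(p$tau_s, p$beta)
  } else if (fit$model == "double_exp") {
    # ties go to the second component (conventionally the slow one)
    i_slow <- if (p$tau2 >= p$tau1) 2L else 1L
    contrib <- c(p$a1 * p$tau1, p$a2 * p$tau2)
    fast <- sum(contrib[-i_slow])
    slow <- contrib[i_slow]
  } else stop("slow_mode_fraction needs a composite (two-mode) fit")
  if (slow == 0) return(0)
  slow / (fast + slow)
}

#' Power-law tail diagnostic for an autocorrelation function
#'
#' Fits a log-log slope over a lag window and scores compensated curves
#' \eqn{t^{|\alpha|} C(t)} for candidate exponents (default -3/2 and -5/2,
#' the hydrodynamic-tail candidates) by the variance of the detrended log.
#' The window is automatically shrunk to strictly positive ACF values and
#' the shrinkage is reported.
#'
#' @param acf a `tensor_acf`.
#' @param candidates candidate exponents.
#' @param window lag window `c(tmin, tmax)` in fs.
#' @return object of class `tail_diagnostic`: `slope`, `slope_se`,
#'   `window_used`, `window_shrunk`, `flatness` (named by candidate),
#'   `best_exponent`, `stable` (slope consistent over window halves).
#' @export
tail_diagnostic <- function(acf, candidates = c(-3 / 2, -5 / 2), window) {
  stopifnot(inherits(acf, "tensor_acf"))
  t <- acf$lag_fs
  y <- acf$value / acf$c0
  sel <- t >= window[1] & t <= window[2] & t > 0
  shrunk <- FALSE
  if (any(y[sel] <= 0)) {
    shrunk <- TRUE
    # keep the largest positive prefix of the window
    bad <- which(sel & y <= 0)
    sel <- sel & t < min(t[bad])
  }
  if (sum(sel) < 5L) stop("fewer than 5 positive points in the tail window")
  lt <- log(t[sel]); ly <- log(y[sel])
  fit <- stats::lm(ly ~ lt)
  slope <- unname(stats::coef(fit)[2])
  slope_se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  # slope drift between window halves marks the absence of a power law
  h <- lt < stats::median(lt)
  s1 <- unname(stats::coef(stats::lm(ly[h] ~ lt[h]))[2])
  s2 <- unname(stats::coef(stats::lm(ly[!h] ~ lt[!h]))[2])
  stable <- abs(s1 - s2) < max(0.25, 3 * slope_se)
  flat <- vapply(candidates, function(a) {
    comp <- ly + abs(a) * lt          # log(t^|a| C)
    stats::var(stats::resid(stats::lm(comp ~ 1)))
  }, numeric(1))
  names(flat) <- sprintf("%g", candidates)
  structure(list(slope = slope, slope_se = slope_se,
                 window_used = range(t[sel]), window_shrunk = shrunk,
                 flatness = flat,
                 best_exponent = candidates[which.min(flat)],
                 stable = stable),
            class = "tail_diagnostic")
}
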