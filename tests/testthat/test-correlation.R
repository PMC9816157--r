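test_that("fft and direct ACF estimators agree to machine precision", {
  x <- withr::with_seed(1, matrix(stats::rnorm(6 * 500), 500, 6))
  a1 <- tensor_acf(x, estimator = "fft", dt = 1)
  a2 <- tensor_acf(x, estimator = "direct", dt = 1)
  expect_lt(max(abs(a1$value - a2$value)) / a1$c0, 1e-10)
})

test_that("ACF of trivial series behaves as expected", {
  # constant tensor: C(t) = C(0) at every lag
  cc <- matrix(rep(c(1, -0.5, -0.5, 0.2, 0, 0), each = 100), 100, 6)
  a <- tensor_acf(cc, dt = 1)
  expect_true(all(abs(a$value - a$c0) < 1e-12))
  # white noise with per-component variance sigma^2: C(0) = 9 sigma^2
  sigma <- 0.7
  x <- withr::with_seed(2, matrix(stats::rnorm(6 * 20000, sd = sigma),
                                  20000, 6))
  aw <- tensor_acf(x, max_lag = 50, dt = 1)
  expect_equal(aw$c0, 9 * sigma^2, tolerance = 0.05)
  expect_lt(max(abs(aw$value[-1])) / aw$c0, 0.05)
  expect_error(tensor_acf(x[1, , drop = FALSE], dt = 1), "at least 2")
})

test_that("OU tensor process recovers its planted decay time", {
  s <- gen_efg_process(process_spec(1, list(list(type = "exp",
                                                 amplitude = 1,
                                                 tau = 500)),
                                    dt = 10, n_frames = 300000, seed = 3))
  a <- tensor_acf(s, max_lag = 2500)
  fit <- fit_acf(a, "fast_exp", window = c(0, 1500))
  expect_equal(fit$par$tau_f, 500, tolerance = 0.03)
})

test_that("correlation time matches closed forms on analytic ACFs", {
  # exponential: tau_c = tau to 0.1%
  t1 <- seq(0, 3000, by = 1)
  ct1 <- correlation_time(analytic_acf(t1, exp(-t1 / 100)),
                          list(method = "full"))
  expect_equal(ct1$tau_c, 100, tolerance = 1e-3)
  # stretched beta = 0.5: tau_c = 2 tau_K
  t2 <- seq(0, 3e5, by = 1)
  ct2 <- correlation_time(analytic_acf(t2, exp(-sqrt(t2 / 1000))),
                          list(method = "full"))
  expect_equal(ct2$tau_c, 2000, tolerance = 5e-3)
  # two-exponential mixture: analytic integral 0.342 ps
  t3 <- seq(0, 20000, by = 0.25)
  ct3 <- correlation_time(analytic_acf(t3, 0.7 * exp(-t3 / 60) +
                                         0.3 * exp(-t3 / 1000)),
                          list(method = "full"))
  expect_equal(ct3$tau_c, 342, tolerance = 5e-3)
  # plateau detection reaches the same answer without a prescribed cutoff
  ct3p <- correlation_time(analytic_acf(t3, 0.7 * exp(-t3 / 60) +
                                          0.3 * exp(-t3 / 1000)))
  expect_equal(ct3p$tau_c, 342, tolerance = 5e-3)
  expect_error(correlation_time(analytic_acf(t1, exp(-t1 / 100)),
                                list(method = "fixed", cutoff = 1e6)),
               "cutoff")
})

test_that("planted fit parameters are recovered and models nest", {
  t <- seq(0, 200, by = 2)
  f1 <- fit_acf(analytic_acf(t, exp(-t / 62)), "fast_exp")
  expect_equal(f1$par$tau_f, 62, tolerance = 0.01)
  ts <- seq(0, 10000, by = 25)
  f2 <- fit_acf(analytic_acf(ts, exp(-(ts / 1000)^0.67)), "stretched")
  expect_equal(f2$par$beta, 0.67, tolerance = 0.02)
  expect_equal(f2$par$tau_s, 1000, tolerance = 0.02)
  # beta pinned at 1 on exponential data reduces to the exponential fit
  te <- seq(0, 2000, by = 10)
  f3 <- fit_acf(analytic_acf(te, exp(-te / 300)), "stretched",
                beta_fixed = 1)
  f4 <- fit_acf(analytic_acf(te, exp(-te / 300)), "fast_exp")
  expect_equal(f3$par$tau_s, f4$par$tau_f, tolerance = 1e-6)
  expect_error(fit_acf(analytic_acf(te[1:8], exp(-te[1:8] / 300)),
                       "fast_plus_stretched"), "5 points")
})

test_that("slow-mode fraction follows the amplitude-weighted mean times", {
  mk_fit <- function(par, model) structure(
    list(model = model, par = par, converged = TRUE), class = "acf_fit")
  # 0.7 @ 0.06 ps + 0.3 @ 1 ps: fraction 0.3 / 0.342
  f <- mk_fit(list(a1 = 0.7, tau1 = 60, a2 = 0.3, tau2 = 1000),
              "double_exp")
  expect_equal(slow_mode_fraction(f), 0.3 / 0.342, tolerance = 1e-10)
  # zero slow amplitude
  f0 <- mk_fit(list(a_f = 1, tau_f = 60, a_s = 0, tau_s = 1000,
                    beta = 0.7), "fast_plus_stretched")
  expect_equal(slow_mode_fraction(f0), 0)
  # equal times: fraction equals the slow amplitude
  fe <- mk_fit(list(a1 = 0.6, tau1 = 100, a2 = 0.4, tau2 = 100),
               "double_exp")
  expect_equal(slow_mode_fraction(fe), 0.4)
  expect_error(slow_mode_fraction(mk_fit(list(a = 1, tau_f = 60),
                                         "fast_exp")), "composite")
})

test_that("composite fit on a sampled two-step process recovers the planted shape", {
  sp <- process_spec(1, list(list(type = "exp", amplitude = 0.7, tau = 62),
                             list(type = "stretched", amplitude = 0.3,
                                  tau = 1000, beta = 0.67)),
                     dt = 10, n_frames = 200000, seed = 7)
  s <- gen_efg_process(sp)
  a <- tensor_acf(s, max_lag = 20000)
  fit <- fit_acf(a, "fast_plus_stretched", window = c(0, 8000))
  expect_equal(fit$par$tau_f, 62, tolerance = 0.05)
  expect_equal(fit$par$beta, 0.67, tolerance = 0.05)
  frac <- slow_mode_fraction(fit)
  frac_true <- 0.3 * 1000 * gamma(1 / 0.67) / 0.67 /
    s$ground_truth$tau_c
  expect_equal(frac, frac_true, tolerance = 0.03)
  # the dominant share of tau_c is carried by the slow mode
  expect_gt(frac, 0.85)
})

test_that("tau_c estimation is monotone in the planted slow time", {
  taus <- c(600, 1000, 1600)
  est <- vapply(taus, function(tk) {
    s <- gen_efg_process(process_spec(
      1, list(list(type = "exp", amplitude = 0.7, tau = 62),
              list(type = "stretched", amplitude = 0.3, tau = tk,
                   beta = 0.67)),
      dt = 10, n_frames = 100000, seed = 21))
    correlation_time(tensor_acf(s, max_lag = 20000))$tau_c
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("tail diagnostic identifies power laws and rejects exponentials", {
  t <- seq(10, 1000, by = 2)
  td <- tail_diagnostic(analytic_acf(t, t^(-2.5), c0 = 1),
                        window = c(50, 500))
  expect_equal(td$slope, -2.5, tolerance = 0.02)
  expect_equal(td$best_exponent, -2.5)
  expect_true(td$stable)
  # exponential data: no stable power-law window
  te <- tail_diagnostic(analytic_acf(t, exp(-t / 50), c0 = 1),
                        window = c(50, 500))
  expect_false(te$stable)
  # stretched + weak tail: exponent recovered only past the crossover
  tt <- seq(1, 40000, by = 4)
  y <- exp(-(tt / 400)^0.67) + 0.01 * (tt / 1000)^(-2.5)
  late <- tail_diagnostic(analytic_acf(tt, y, c0 = 1),
                          window = c(26000, 40000))
  expect_equal(late$slope, -2.5, tolerance = 0.05)
  early <- tail_diagnostic(analytic_acf(tt, y, c0 = 1),
                           window = c(500, 3000))
  expect_gt(abs(early$slope - (-2.5)), 0.3)
  # non-positive values shrink the window and report it
  yz <- exp(-tt / 300) - 0.001
  tz <- tail_diagnostic(analytic_acf(tt, yz, c0 = 1),
                        window = c(100, 30000))
  expect_true(tz$window_shrunk)
})

test_that("a correctly specified model leaves no systematic residual", {
  s <- gen_efg_process(process_spec(1, list(list(type = "exp",
                                                 amplitude = 1,
                                                 tau = 300)),
                                    dt = 20, n_frames = 150000, seed = 9))
  a <- tensor_acf(s, max_lag = 2000)
  fit <- fit_acf(a, "fast_exp")
  resid <- a$value / a$c0 - fit$par$a * exp(-a$lag_fs / fit$par$tau_f)
  # neighbouring lag estimates share data, so residuals are correlated
  # even for the true model; the check is on their size, not whiteness
  expect_lt(max(abs(resid)), 0.02)
  expect_lt(abs(mean(resid)), 3 * stats::sd(resid) / sqrt(length(resid)) +
              1e-3)
})
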