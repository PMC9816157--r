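test_that("stress ACF kills isotropic pressure and antisymmetric parts", {
  n <- 2000
  base <- gen_maxwell_stress(G = 1e10, tau = 100, dt = 1, n_frames = n,
                             volume = 1e-26, temperature = 300, seed = 1)
  shifted <- base
  for (r in 1:3) shifted$stress[, r, r] <- shifted$stress[, r, r] + 5e6
  a1 <- stress_acf(base, max_lag = 200)
  a2 <- stress_acf(shifted, max_lag = 200)
  expect_equal(a1$value, a2$value, tolerance = 1e-12)
  noisy <- gen_maxwell_stress(G = 1e10, tau = 100, dt = 1, n_frames = n,
                              volume = 1e-26, temperature = 300,
                              antisym_sd = 1e6, seed = 1)
  a3 <- stress_acf(noisy, max_lag = 200)
  expect_equal(a1$value, a3$value, tolerance = 1e-12)
  # pure pressure carries no shear signal at all
  iso <- stress_series(array(rep(diag(3) * 1e6, each = 100),
                             c(100, 3, 3)), 1, 1e-26, 300)
  expect_equal(stress_acf(iso, max_lag = 10)$c0, 0)
})

test_that("Green-Kubo viscosity matches the Maxwell closed form", {
  # analytic ACF: eta = V G tau / kB T exactly
  V <- 2.7e-26; G <- 1e10; tau <- 200; temp <- 300
  t <- seq(0, 4000, by = 1)
  acf <- analytic_acf(t, G * exp(-t / tau))
  acf$volume <- V; acf$temperature <- temp
  gk <- green_kubo_viscosity(acf, cutoff_policy = list(method = "full"))
  eta_exact <- V * G * tau * 1e-15 / (physical_constants$k_B * temp)
  expect_equal(gk$eta, eta_exact, tolerance = 1e-3)
  # zero stress
  zero <- stress_series(array(0, c(100, 3, 3)), 1, V, temp)
  expect_equal(green_kubo_viscosity(stress_acf(zero, max_lag = 10))$eta, 0)
  # sampled Maxwell modes recover the planted viscosity
  ms <- gen_maxwell_stress(G = G, tau = tau, dt = 1, n_frames = 500000,
                           volume = V, temperature = temp, seed = 2)
  gs <- green_kubo_viscosity(stress_acf(ms, max_lag = 4000))
  expect_equal(gs$eta, ms$ground_truth$eta_pa_s, tolerance = 0.05)
})

test_that("MSD diffusion recovers Brownian walkers and rejects ballistic data", {
  bw <- gen_brownian_walkers(D = 1e-3, n = 64, dt = 10, n_steps = 5000,
                             seed = 4)
  d <- msd_diffusion(bw$traj, bw$dt)
  expect_equal(d$D_angstrom_fs, 1e-3, tolerance = 0.05)
  expect_equal(d$D, bw$ground_truth$D_m2s, tolerance = 0.05)
  expect_gt(d$r_squared, 0.99)
  # static particles: D = 0
  still <- array(1, c(100, 3, 2))
  expect_equal(msd_diffusion(still, 1)$D, 0)
  # ballistic motion fails the diffusive-regime check
  tvec <- 0:999
  ball <- array(0, c(1000, 3, 1)); for (a in 1:3) ball[, a, 1] <- 0.1 * tvec
  expect_error(msd_diffusion(ball, 1), "diffusive")
})

test_that("Yeh-Hummer correction is exact arithmetic with the right limits", {
  D <- 1.0e-9; eta <- 0.89e-3; temp <- 298.15; L <- 3.1e-9
  xi <- as.numeric(xi_cubic())
  yh <- yeh_hummer_correct(D, eta, temp, L, xi = xi)
  corr_exact <- physical_constants$k_B * temp * xi / (6 * pi * eta * L)
  expect_equal(yh$correction, corr_exact, tolerance = 1e-14)
  expect_equal(yh$D_inf, D + corr_exact, tolerance = 1e-14)
  # L -> infinity: no correction
  expect_equal(yeh_hummer_correct(D, eta, temp, 1e6)$D_inf, D,
               tolerance = 1e-6)
  # box sizes tuned to the 17-22% regime reproduce that fraction exactly
  for (target in c(0.17, 0.22)) {
    L_t <- physical_constants$k_B * temp * xi / (6 * pi * eta * target * D)
    expect_equal(yeh_hummer_correct(D, eta, temp, L_t)$fraction, target,
                 tolerance = 1e-12)
  }
})

test_that("the cubic lattice constant is 2.837297 and parameter-invariant", {
  xi <- xi_cubic()
  expect_equal(as.numeric(xi), 2.837297, tolerance = 1e-6 / 2.837297)
  expect_true(attr(xi, "converged"))
  expect_lt(abs(xi_cubic(alpha = 1) - xi_cubic(alpha = 2)), 1e-8)
  # deliberate under-convergence raises the flag
  expect_warning(xi_bad <- xi_cubic(alpha = 8, max_shell = 1L),
                 "not converged")
  expect_gt(abs(xi_bad - 2.837297), 1e-3)
})

test_that("Stokes radius and SED time follow their defining formulas", {
  D <- 1.33e-9; eta <- 0.89e-3; temp <- 298.15
  r0 <- stokes_radius(D, eta, temp)
  expect_equal(r0, physical_constants$k_B * temp / (6 * pi * eta * D),
               tolerance = 1e-14)
  expect_gt(r0 * 1e10, 1.5); expect_lt(r0 * 1e10, 2.0)
  # doubling eta at fixed D halves r0
  expect_equal(stokes_radius(D, 2 * eta, temp), r0 / 2, tolerance = 1e-14)
  ts <- sed_time(eta, 2.0e-10, temp)
  expect_equal(ts, 4 * pi * eta * (2e-10)^3 /
                 (3 * physical_constants$k_B * temp), tolerance = 1e-14)
  expect_gt(ts * 1e12, 6); expect_lt(ts * 1e12, 8)
  # cubic scaling in r0; inverse in T at fixed eta
  expect_equal(sed_time(eta, 4e-10, temp), 8 * ts, tolerance = 1e-12)
  expect_equal(sed_time(eta, 2e-10, 2 * temp), ts / 2, tolerance = 1e-12)
})

test_that("effective SED fit inverts its generating model", {
  r0 <- 0.69e-10; tau0 <- 0.11e-12
  temps <- c(283, 293, 298, 303, 313, 323)
  etas <- c(1.3, 1.0, 0.89, 0.8, 0.65, 0.55) * 1e-3
  x <- etas / (physical_constants$k_B * temps)
  tau <- 4 * pi * r0^3 / 3 * x + tau0
  fit <- effective_sed_fit(tau, x)
  expect_equal(fit$r0_eff, r0, tolerance = 1e-10)
  expect_equal(fit$tau0_eff, tau0, tolerance = 1e-10)
  # slope ~ zero: vanishing radius, intercept the mean
  fit0 <- suppressWarnings(
    effective_sed_fit(rep(2e-13, 4), c(1, 2, 3, 4) * 1e17))
  expect_true(is.na(fit0$r0_eff) || fit0$r0_eff < 1e-11)
  expect_equal(fit0$tau0_eff, 2e-13, tolerance = 1e-6)
  expect_warning(effective_sed_fit(rev(seq_len(4)) * 1e-13,
                                   seq_len(4) * 1e17), "negative slope")
  expect_error(effective_sed_fit(1:2 * 1e-13, 1:2), "at least 3")
})

test_that("noisy effective SED fits recover the radius within 2 SE usually", {
  r0 <- 0.69e-10; tau0 <- 0.11e-12
  x <- seq(2e20, 6e20, length.out = 8)
  tau_true <- 4 * pi * r0^3 / 3 * x + tau0
  hits <- 0L
  for (r in 1:20) {
    tau_obs <- withr::with_seed(700 + r,
                                tau_true * (1 + 0.1 * stats::rnorm(8)))
    fit <- suppressWarnings(effective_sed_fit(tau_obs, x))
    if (!is.na(fit$r0_eff)) {
      slope_true <- 4 * pi * r0^3 / 3
      if (abs(fit$slope - slope_true) <= 2 * fit$slope_se) hits <- hits + 1L
    }
  }
  expect_gte(hits, 18L * 0.9)
})

test_that("dipole reorientation time matches the rotational-diffusion oracle", {
  rot <- gen_rotational_diffusion(D_r = 5e-4, n_vectors = 40, dt = 20,
                                  n_frames = 8000, seed = 2)
  # long noise-dominated tail triggers the cutoff diagnostics; the
  # estimate itself is checked against the planted value below
  td <- suppressWarnings(dipole_reorientation_time(rot$orient, rot$dt))
  expect_equal(td$tau_dip_fs, rot$ground_truth$tau_dip_fs, tolerance = 0.03)
  # frozen vectors: flagged divergence
  frozen <- gen_rotational_diffusion(D_r = 0, n_vectors = 5, dt = 10,
                                     n_frames = 200, seed = 3)
  expect_warning(tf <- dipole_reorientation_time(frozen$orient, 10),
                 "not decayed")
  expect_false(tf$decayed)
  # memoryless limit: independent vectors each frame
  fresh <- array(stats::rnorm(300 * 3 * 10), c(300, 3, 10))
  nrm <- sqrt(fresh[, 1, ]^2 + fresh[, 2, ]^2 + fresh[, 3, ]^2)
  for (a in 1:3) fresh[, a, ] <- fresh[, a, ] / nrm
  tm <- dipole_reorientation_time(fresh, dt = 10)
  expect_lt(tm$tau_dip_fs, 10)
})

test_that("structural relaxation time recovers planted stretched tails", {
  # Gamma-function identities
  fitb1 <- structure(list(tau_K_fs = 400, beta_K = 1), class = "x")
  expect_equal(quadrelax:::stretched_mean_time(400, 1), 400)
  expect_equal(quadrelax:::stretched_mean_time(400, 0.5), 800)
  # planted stretched stress tail: recover tau_K, beta_K within 5%
  tau_k <- 400; beta_k <- 0.61
  t <- seq(0, 20000, by = 5)
  cv <- 1e10 * exp(-(t / tau_k)^beta_k)
  acf <- analytic_acf(t, cv)
  sr <- structural_relaxation_time(acf, tail_window = c(100, 15000))
  expect_equal(sr$tau_K_fs, tau_k, tolerance = 0.05)
  expect_equal(sr$beta_K, beta_k, tolerance = 0.05)
  # Gamma formula matches numerical quadrature of the planted form
  quad <- stats::integrate(function(u) exp(-(u / tau_k)^beta_k), 0, Inf)
  expect_equal(sr$tau_struct_fs, quad$value, tolerance = 0.01)
  expect_equal(sr$tau_struct_fs,
               sr$tau_K_fs * gamma(1 / sr$beta_K) / sr$beta_K,
               tolerance = 1e-10)
})

test_that("slowing every planted mode by s scales every estimated time by s", {
  run_times <- function(s) {
    efg <- gen_efg_process(process_spec(
      1, list(list(type = "exp", amplitude = 0.7, tau = 62 * s),
              list(type = "stretched", amplitude = 0.3, tau = 800 * s,
                   beta = 0.7)),
      dt = 10 * s, n_frames = 100000, seed = 31))
    tau_c <- correlation_time(tensor_acf(efg, max_lag = 15000 * s))$tau_c
    rot <- gen_rotational_diffusion(D_r = 5e-4 / s, n_vectors = 30,
                                    dt = 20 * s, n_frames = 5000,
                                    seed = 32)
    tau_dip <- dipole_reorientation_time(rot$orient, rot$dt)$tau_dip_fs
    c(tau_c = tau_c, tau_dip = tau_dip)
  }
  t1 <- run_times(1)
  t3 <- run_times(3)
  expect_equal(unname(t3 / t1), c(3, 3), tolerance = 0.06)
})
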