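# Internal MD units for the toy Langevin generator: length Angstrom, time
# fs, mass u. Derived: energy u A^2/fs^2 = 1.66054e-17 J; Coulomb constant
# e^2/(4 pi eps0) = 0.138935 u A^3/fs^2; k_B = 8.31446e-7 (u A^2/fs^2)/K;
# stress unit u/(A fs^2) = 1.66054e13 Pa.
.md_units <- list(
  kb = 1.380649e-23 / 1.66053906660e-17,
  coulomb = 0.1389354576,
  stress_to_pa = 1.66053906660e13,
  d_to_m2s = 1e-5           # Angstrom^2/fs -> m^2/s
)

#' Specification of a stationary tensor process with a prescribed ACF
#'
#' Defines the target normalized ACF as a mixture of exponential and
#' stretched-exponential modes, mirroring the two-step relaxation observed
#' for ionic EFGs: a fast (~tens of fs) exponential plus a slow (~ps)
#' stretched mode.
#'
#' @param variance target Frobenius variance \eqn{\langle V:V\rangle}.
#' @param modes list of modes, each `list(type = "exp"|"stretched",
#'   amplitude, tau, beta)` (tau in fs; beta only for stretched).
#'   Amplitudes are normalized to sum to 1.
#' @param dt sampling interval (fs).
#' @param n_frames number of frames.
#' @param seed generator seed.
#' @return object of class `process_spec`.
#' @export
process_spec <- function(variance, modes, dt, n_frames, seed = 0L) {
  if (variance <= 0) stop("variance must be positive")
  amps <- vapply(modes, function(m) m$amplitude, numeric(1))
  if (any(amps <= 0)) stop("mode amplitudes must be positive")
  for (m in modes) {
    if (!m$type %in% c("exp", "stretched")) stop("unknown mode type")
    if (m$tau <= 0) stop("mode time constants must be positive")
    if (m$type == "stretched" &&
        (is.null(m$beta) || m$beta <= 0 || m$beta > 1))
      stop("stretched modes need beta in (0, 1]")
  }
  modes <- lapply(modes, function(m) { m$amplitude <- m$amplitude /
    sum(amps); m })
  structure(list(variance = variance, modes = modes, dt = dt,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "process_spec")
}

# analytic normalized target ACF of a spec
spec_target_acf <- function(spec) {
  function(t) {
    out <- 0
    for (m in spec$modes)
      out <- out + if (m$type == "exp") m$amplitude * exp(-t / m$tau)
        else m$amplitude * exp(-(t / m$tau)^m$beta)
    out
  }
}

# analytic tau_c of a spec: sum of amplitude-weighted mean mode times
spec_tau_c <- function(spec) {
  sum(vapply(spec$modes, function(m)
    m$amplitude * if (m$type == "exp") m$tau
    else stretched_mean_time(m$tau, m$beta), numeric(1)))
}

# Prony (multi-exponential) approximation of a stretched exponential:
# nonnegative weights over a log-spaced rate grid, constrained to sum to 1,
# fitted in sup-norm-controlled least squares on log-spaced lags.
prony_stretched <- function(tau, beta, dt, n_exp = 48L, sup_tol = 0.01) {
  tau_grid <- exp(seq(log(max(dt / 4, tau * 1e-3)), log(tau * 316),
                      length.out = n_exp))
  t_max <- tau * (-log(1e-7))^(1 / beta)
  lags <- unique(c(0, exp(seq(log(dt / 4), log(t_max), length.out = 400))))
  target <- exp(-(lags / tau)^beta)
  a <- exp(-outer(lags, 1 / tau_grid))          # design matrix
  # weight the sum-to-one constraint heavily (exact C(0) matters most)
  aa <- rbind(a, 100 * rep(1, n_exp))
  bb <- c(target, 100)
  w <- pracma::lsqnonneg(aa, bb)$x
  w <- w / sum(w)
  err <- max(abs(a %*% w - target))
  if (err > sup_tol)
    stop(sprintf(paste0("stretched mode (tau = %g fs, beta = %g) not ",
                        "representable at dt = %g fs: Prony sup-norm error ",
                        "%.3g"), tau, beta, dt, err))
  list(tau = tau_grid, weight = w, sup_error = err)
}

# stationary OU sample of length n with unit variance and time constant tau
ou_sample <- function(n, tau, dt) {
  rho <- exp(-dt / tau)
  innov <- stats::rnorm(n, sd = sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = stats::rnorm(1)))
}

#' Generate a symmetric-traceless tensor process with a prescribed ACF
#'
#' Five independent scalar processes are mapped onto an orthonormal basis of
#' the symmetric-traceless tensor space, so every frame is exactly traceless
#' and the Frobenius ACF equals the (shared) scalar ACF times the variance.
#' Exponential modes use the exact Ornstein-Uhlenbeck recursion; stretched
#' modes are realized as finite Prony (multi-exponential) superpositions
#' matching the target ACF to a recorded sup-norm tolerance, since exact
#' stationary stretched processes are not Markovian.
#'
#' @param spec a [process_spec].
#' @return an `efg_series` whose `ground_truth` field records the spec, the
#'   analytic `tau_c` (fs), the realized (Prony) `tau_c`, the target ACF
#'   function and the Prony sup-norm error.
#' @export
gen_efg_process <- function(spec) {
  stopifnot(inherits(spec, "process_spec"))
  local_rng(spec$seed)
  n <- spec$n_frames
  # expand modes into elementary exponentials
  taus <- numeric(0); weights <- numeric(0); sup_err <- 0
  for (m in spec$modes) {
    if (m$type == "exp") {
      taus <- c(taus, m$tau); weights <- c(weights, m$amplitude)
    } else {
      pr <- prony_stretched(m$tau, m$beta, spec$dt)
      keep <- pr$weight > 1e-12
      taus <- c(taus, pr$tau[keep])
      weights <- c(weights, m$amplitude * pr$weight[keep])
      sup_err <- max(sup_err, pr$sup_error)
    }
  }
  s_var <- spec$variance / 5            # per-scalar variance
  scalars <- matrix(0, n, 5L)
  for (i in 1:5) {
    x <- numeric(n)
    for (j in seq_along(taus))
      x <- x + sqrt(weights[j]) * ou_sample(n, taus[j], spec$dt)
    scalars[, i] <- sqrt(s_var) * x
  }
  basis_comps <- t(vapply(traceless_basis(), tensor_to_comps, numeric(6)))
  comps <- scalars %*% basis_comps
  colnames(comps) <- tensor_comp_names
  gt <- list(spec = spec,
             variance = spec$variance,
             tau_c = spec_tau_c(spec),
             tau_c_realized = sum(weights * taus),
             target_acf = spec_target_acf(spec),
             prony_sup_error = sup_err)
  new_efg_series(comps, spec$dt, probes = 1L, ground_truth = gt)
}

#' Specification of the toy Langevin ionic fluid
#'
#' A deliberately simple stand-in system: soft repulsive spheres with
#' alternating +q/-q charges in a cubic periodic box, integrated with a
#' BAOAB Langevin scheme. It exercises the EFG, stress and diffusion
#' plumbing end to end with physically structured data; it makes no claim
#' to reproduce any production force field.
#'
#' @param n even number of particles (alternating charges, neutral).
#' @param charge charge magnitude (e).
#' @param sigma soft-sphere diameter (Angstrom).
#' @param epsilon soft-sphere energy scale (u A^2/fs^2); default about one
#'   k_B T at 300 K.
#' @param box_edge cubic box edge (Angstrom).
#' @param temperature temperature (K).
#' @param friction Langevin friction (1/fs).
#' @param mass particle mass (u).
#' @param dt timestep (fs); checked against the soft-sphere oscillation
#'   period (must be below 2 percent of it).
#' @param n_steps number of integration steps.
#' @param sample_every sampling stride (frames).
#' @param seed integer seed.
#' @return object of class `toy_system_spec`.
#' @export
toy_system_spec <- function(n = 16L, charge = 1, sigma = 2.5,
                            epsilon = 2.5e-4, box_edge = 10,
                            temperature = 298.15, friction = 0.02,
                            mass = 30, dt = 1, n_steps = 2000L,
                            sample_every = 5L, seed = 0L) {
  if (n %% 2L != 0L) stop("n must be even for a neutral alternating system")
  # curvature of the r^-12 wall at contact sets the fastest oscillation
  omega <- sqrt(156 * epsilon / sigma^2 / mass)
  if (dt >= 0.02 * 2 * pi / omega)
    stop(sprintf("dt = %g fs violates the stability bound %.3g fs",
                 dt, 0.02 * 2 * pi / omega))
  structure(list(n = as.integer(n), charge = charge, sigma = sigma,
                 epsilon = epsilon, box_edge = box_edge,
                 temperature = temperature, friction = friction,
                 mass = mass, dt = dt, n_steps = as.integer(n_steps),
                 sample_every = as.integer(sample_every),
                 seed = as.integer(seed)),
            class = "toy_system_spec")
}

#' Toy Langevin trajectory of a charged soft-sphere fluid
#'
#' BAOAB velocity-Verlet Langevin integration of soft spheres with damped
#' (complementary-error-function-screened) minimum-image Coulomb forces.
#' Emits wrapped configurations (for EFG analysis), unwrapped positions
#' (for diffusion), per-frame virial stress in Pascal, and kinetic
#' temperature diagnostics. Energy blow-up is detected and raised.
#'
#' @param spec a [toy_system_spec].
#' @return list with `traj` (list of [configuration]), `unwrapped`
#'   (array n_frames x 3 x n, Angstrom), `stress` ([stress_series], Pa),
#'   `kinetic_temperature` (per-frame, K), `spec`, `ground_truth` (list:
#'   `temperature`, `D_overdamped_m2s` = k_B T / (m gamma)).
#' @export
gen_langevin_trajectory <- function(spec) {
  stopifnot(inherits(spec, "toy_system_spec"))
  local_rng(spec$seed)
  n <- spec$n; L <- spec$box_edge; dtv <- spec$dt
  kbt <- .md_units$kb * spec$temperature
  m <- spec$mass
  q <- rep(c(spec$charge, -spec$charge), n / 2)
  species <- rep(c("Na", "Cl"), n / 2)
  kappa <- 8 / L                     # Coulomb damping: negligible at L/2
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  qq <- .md_units$coulomb * q[pairs[, 1]] * q[pairs[, 2]]

  forces <- function(x) {
    d <- x[pairs[, 1], ] - x[pairs[, 2], ]
    d <- d - round(d / L) * L
    r2 <- rowSums(d * d)
    r <- sqrt(r2)
    f_ss <- 12 * spec$epsilon * (spec$sigma^12 / r2^6) / r2
    f_c <- qq * (pracma::erfc(kappa * r) / r2 +
                   2 * kappa / sqrt(pi) * exp(-kappa^2 * r2) / r) / r
    fmag <- f_ss + f_c               # positive = repulsive, along d
    fv <- d * fmag
    f <- matrix(0, n, 3)
    for (a in 1:3)
      f[, a] <- rowsum_accumulate(fv[, a], pairs[, 1], n) -
        rowsum_accumulate(fv[, a], pairs[, 2], n)
    virial <- crossprod(d, fv)       # sum_pairs d_a f_b
    list(f = f, virial = virial)
  }

  # start from a perturbed cubic lattice to avoid overlaps
  g <- ceiling(n^(1 / 3))
  lat <- as.matrix(expand.grid(seq_len(g), seq_len(g), seq_len(g)))[1:n, ]
  x <- (lat - 0.5) * (L / g) + matrix(stats::rnorm(3 * n, sd = 0.05), n, 3)
  x_unwrap <- x
  v <- matrix(stats::rnorm(3 * n, sd = sqrt(kbt / m)), n, 3)
  fr <- forces(x)
  c1 <- exp(-spec$friction * dtv)
  c2 <- sqrt((1 - c1^2) * kbt / m)
  n_samp <- spec$n_steps %/% spec$sample_every
  traj <- vector("list", n_samp)
  unwrapped <- array(NA_real_, c(n_samp, 3L, n))
  stress <- array(NA_real_, c(n_samp, 3L, 3L))
  kin_t <- numeric(n_samp)
  isamp <- 0L
  for (step in seq_len(spec$n_steps)) {
    v <- v + fr$f / m * (dtv / 2)
    dx <- v * (dtv / 2); x_unwrap <- x_unwrap + dx; x <- (x + dx) %% L
    v <- c1 * v + c2 * matrix(stats::rnorm(3 * n), n, 3)
    dx <- v * (dtv / 2); x_unwrap <- x_unwrap + dx; x <- (x + dx) %% L
    fr <- forces(x)
    v <- v + fr$f / m * (dtv / 2)
    ke_dof <- m * mean(v^2) / 2
    if (!is.finite(ke_dof) || ke_dof > 100 * kbt)
      stop(sprintf("Langevin integration unstable at step %d", step))
    if (step %% spec$sample_every == 0L) {
      isamp <- isamp + 1L
      traj[[isamp]] <- configuration(x, q, L, species = species,
                                     time = step * dtv)
      unwrapped[isamp, , ] <- t(x_unwrap)
      kin_t[isamp] <- ke_dof / (.md_units$kb / 2)   # kinetic temperature, K
      stress[isamp, , ] <- (m * crossprod(v) + fr$virial) / L^3 *
        .md_units$stress_to_pa
    }
  }
  list(traj = traj, unwrapped = unwrapped,
       stress = stress_series(stress, dtv * spec$sample_every,
                              volume = L^3 * 1e-30,
                              temperature = spec$temperature),
       kinetic_temperature = kin_t, spec = spec,
       ground_truth = list(
         temperature = spec$temperature,
         D_overdamped_m2s = kbt / (m * spec$friction) * .md_units$d_to_m2s))
}

# sum values by integer group id into a length-n vector
rowsum_accumulate <- function(values, ids, n) {
  out <- numeric(n)
  agg <- rowsum(values, ids)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Maxwell-mode synthetic stress series
#'
#' Five independent Ornstein-Uhlenbeck amplitudes on the symmetric-traceless
#' basis give a stress ACF \eqn{C_{stress}(t) = G e^{-t/\tau}}; an optional
#' isotropic pressure offset and antisymmetric noise exercise the
#' invariances of [stress_acf]. The Green-Kubo viscosity of the planted
#' model is \eqn{\eta = V G \tau / k_B T}.
#'
#' @param G stress ACF amplitude C(0) (Pa^2).
#' @param tau Maxwell relaxation time (fs).
#' @param dt sampling interval (fs).
#' @param n_frames number of frames.
#' @param volume box volume (m^3).
#' @param temperature temperature (K).
#' @param pressure_offset constant isotropic offset added to the stress (Pa).
#' @param antisym_sd standard deviation of added antisymmetric noise (Pa).
#' @param seed integer seed.
#' @return a [stress_series] with `ground_truth` attribute (list `G`,
#'   `tau`, `eta_pa_s`).
#' @export
gen_maxwell_stress <- function(G, tau, dt, n_frames, volume, temperature,
                               pressure_offset = 0, antisym_sd = 0,
                               seed = 0L) {
  local_rng(seed)
  n <- as.integer(n_frames)
  s_amp <- sqrt(2 * G)               # per-scalar sd so that C(0) = G
  basis <- traceless_basis()
  stress <- array(0, c(n, 3L, 3L))
  for (i in 1:5) {
    a <- s_amp * ou_sample(n, tau, dt)
    for (r in 1:3) for (cc in 1:3)
      stress[, r, cc] <- stress[, r, cc] + a * basis[[i]][r, cc]
  }
  if (pressure_offset != 0)
    for (r in 1:3) stress[, r, r] <- stress[, r, r] + pressure_offset
  if (antisym_sd > 0) {
    w <- matrix(stats::rnorm(3L * n, sd = antisym_sd), n, 3L)
    stress[, 1, 2] <- stress[, 1, 2] + w[, 1]
    stress[, 2, 1] <- stress[, 2, 1] - w[, 1]
    stress[, 1, 3] <- stress[, 1, 3] + w[, 2]
    stress[, 3, 1] <- stress[, 3, 1] - w[, 2]
    stress[, 2, 3] <- stress[, 2, 3] + w[, 3]
    stress[, 3, 2] <- stress[, 3, 2] - w[, 3]
  }
  out <- stress_series(stress, dt, volume, temperature)
  out$ground_truth <- list(
    G = G, tau = tau,
    eta_pa_s = volume * G * tau * 1e-15 /
      (physical_constants$k_B * temperature))
  out
}

#' Brownian rotors on the unit sphere
#'
#' Isotropic rotational diffusion with coefficient `D_r`: each step rotates
#' every vector by a Gaussian tangential angle, preserving unit norm
#' exactly. The first-rank orientational correlation decays as
#' \eqn{e^{-2 D_r t}}, so the planted reorientation time is
#' \eqn{\tau_{dip} = 1/(2 D_r)}.
#'
#' @param D_r rotational diffusion coefficient (1/fs); `D_r * dt` must be
#'   well below 1.
#' @param n_vectors number of independent rotors.
#' @param dt sampling interval (fs).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return list `orient` (array n_frames x 3 x n_vectors),
#'   `ground_truth` (`D_r`, `tau_dip_fs` = 1/(2 D_r)), `dt`.
#' @export
gen_rotational_diffusion <- function(D_r, n_vectors, dt, n_frames,
                                     seed = 0L) {
  if (D_r < 0) stop("D_r must be non-negative")
  if (D_r * dt > 0.05)
    stop("D_r * dt too large for the small-step rotation scheme")
  local_rng(seed)
  n <- as.integer(n_frames); nv <- as.integer(n_vectors)
  u <- matrix(stats::rnorm(3 * nv), nv, 3)
  u <- u / sqrt(rowSums(u * u))
  orient <- array(NA_real_, c(n, 3L, nv))
  sd_step <- sqrt(2 * D_r * dt)
  for (i in seq_len(n)) {
    orient[i, , ] <- t(u)
    if (D_r == 0) next
    # orthonormal tangent frame at each u
    ref <- matrix(rep(c(1, 0, 0), each = nv), nv, 3)
    swap <- abs(u[, 1]) > 0.9
    ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), sum(swap), 3)
    e1 <- ref - u * rowSums(ref * u)
    e1 <- e1 / sqrt(rowSums(e1 * e1))
    e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
                u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
                u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
    w1 <- stats::rnorm(nv, sd = sd_step)
    w2 <- stats::rnorm(nv, sd = sd_step)
    theta <- sqrt(w1^2 + w2^2)
    that <- (e1 * w1 + e2 * w2) / ifelse(theta > 0, theta, 1)
    u <- u * cos(theta) + that * sin(theta)
    u <- u / sqrt(rowSums(u * u))
  }
  list(orient = orient, dt = dt,
       ground_truth = list(D_r = D_r,
                           tau_dip_fs = if (D_r > 0) 1 / (2 * D_r)
                                        else Inf))
}

#' Synthetic classical/ab-initio EFG pair table
#'
#' Builds \eqn{V_{AI} = (1+\gamma) V_{ext} + N} from an EFG series, where N
#' is independent symmetric-traceless noise whose Frobenius variance is
#' `noise_level^2` times that of \eqn{(1+\gamma)V_{ext}}. With that
#' convention the variance-ratio factor is inflated over the slope factor by
#' exactly \eqn{\sqrt{1 + \nu^2}}.
#'
#' @param series an `efg_series` providing the external EFG frames.
#' @param gamma planted Sternheimer enhancement (slope = 1 + gamma).
#' @param noise_level relative noise magnitude nu (>= 0).
#' @param seed integer seed.
#' @return an [efg_pair_table] with `ground_truth` attribute (`gamma`,
#'   `noise_level`, `expected_inflation` = sqrt(1 + nu^2)).
#' @export
gen_pair_table <- function(series, gamma, noise_level = 0, seed = 0L) {
  if (noise_level < 0) stop("noise_level must be non-negative")
  local_rng(seed)
  d <- dim(series$comps)
  v_ext_var <- efg_variance(series)
  s_n <- sqrt(noise_level^2 * (1 + gamma)^2 * v_ext_var / 5)
  basis_comps <- t(vapply(traceless_basis(), tensor_to_comps, numeric(6)))
  recs <- vector("list", d[3])
  for (j in seq_len(d[3])) {
    vx <- series$comps[, , j, drop = TRUE]
    noise <- (matrix(stats::rnorm(d[1] * 5, sd = s_n), d[1], 5) %*%
                basis_comps)
    vai <- (1 + gamma) * vx + noise
    recs[[j]] <- data.frame(
      config_id = rep(seq_len(d[1]), times = 6L),
      probe_id = j,
      comp = rep(tensor_comp_names, each = d[1]),
      v_ext = as.vector(vx), v_ai = as.vector(vai))
  }
  tab <- do.call(rbind, recs)
  out <- efg_pair_table(tab$config_id, tab$probe_id, tab$comp, tab$v_ext,
                        tab$v_ai)
  attr(out, "ground_truth") <- list(gamma = gamma,
                                    noise_level = noise_level,
                                    expected_inflation =
                                      sqrt(1 + noise_level^2))
  out
}

#' Ideal Brownian walkers
#'
#' Independent Gaussian increments of variance \eqn{2 D\,dt} per dimension:
#' the exact simulation of free diffusion, used as the oracle for
#' [msd_diffusion].
#'
#' @param D diffusion coefficient (Angstrom^2/fs).
#' @param n number of walkers.
#' @param dt timestep (fs).
#' @param n_steps number of steps.
#' @param seed integer seed.
#' @return list `traj` (array (n_steps + 1) x 3 x n, unwrapped Angstrom),
#'   `dt`, `ground_truth` (`D_angstrom_fs`, `D_m2s`).
#' @export
gen_brownian_walkers <- function(D, n, dt, n_steps, seed = 0L) {
  if (D < 0 || dt <= 0) stop("D must be >= 0 and dt > 0")
  local_rng(seed)
  nf <- as.integer(n_steps) + 1L
  traj <- array(0, c(nf, 3L, n))
  sd_step <- sqrt(2 * D * dt)
  for (w in seq_len(n))
    for (a in 1:3)
      traj[, a, w] <- c(0, cumsum(stats::rnorm(n_steps, sd = sd_step)))
  list(traj = traj, dt = dt,
       ground_truth = list(D_angstrom_fs = D, D_m2s = D * .md_units$d_to_m2s))
}
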