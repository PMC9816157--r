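test_that("direct sum reproduces closed-form point-charge EFGs", {
  # single +1e charge 2 A above the probe: V_zz = 2q/r^3 = 0.25 e/A^3
  cfg <- configuration(rbind(c(0, 0, 0), c(0, 0, 2)), c(0, 1), 40)
  v <- efg_direct_sum(cfg, 1, image_shells = 0)
  expect_equal(v[3, 3], 0.25, tolerance = 1e-12)
  expect_equal(v[1, 1], -0.125, tolerance = 1e-12)
  expect_equal(v[2, 2], -0.125, tolerance = 1e-12)
  expect_equal(max(abs(v[upper.tri(v)])), 0)
  # superposition: charges at (0,0,+-2) double V_zz
  cfg2 <- configuration(rbind(c(20, 20, 20), c(20, 20, 22), c(20, 20, 18)),
                        c(0, 1, 1), 40)
  expect_equal(efg_direct_sum(cfg2, 1, 0)[3, 3], 0.5, tolerance = 1e-12)
  # source on top of the probe is a singularity
  cfg3 <- configuration(rbind(c(0, 0, 0), c(0, 0, 1e-8)), c(0, 1), 40)
  expect_error(efg_direct_sum(cfg3, 1, 0), "1e-6 Angstrom")
})

test_that("cubic site symmetry forbids an EFG at rock-salt lattice sites", {
  rs <- rock_salt_config()
  expect_lt(max(abs(efg_direct_sum(rs, 1, 6))), 5e-7)
  expect_lt(max(abs(efg_ewald(rs, 1)[[1]])), 1e-8)
})

test_that("Ewald EFG matches the converged direct-sum oracle", {
  for (seed in 1:3) {
    cfg <- random_config(64, 12, seed)
    oracle <- efg_direct_sum_converged(cfg, 1)
    ew <- efg_ewald(cfg, 1)[[1]]
    expect_lt(rel_diff(ew, oracle), 1e-6)
  }
})

test_that("Ewald result is invariant to the splitting parameter", {
  cfg <- random_config(64, 12, 5)
  vs <- lapply(c(0.25, 0.35, 0.45), function(a)
    efg_ewald(cfg, 1, ewald_params(12, alpha = a))[[1]])
  expect_lt(rel_diff(vs[[1]], vs[[3]]), 1e-8)
  expect_lt(rel_diff(vs[[2]], vs[[3]]), 1e-8)
})

test_that("every EFG tensor is symmetric and traceless", {
  cfg <- random_config(48, 10, 6)
  for (p in c(1L, 7L, 20L)) {
    v <- efg_ewald(cfg, p)[[1]]
    expect_silent(check_efg_tensor(v))
  }
  v <- efg_direct_sum(cfg, 3, 4)
  expect_lt(abs(sum(diag(v))) / sqrt(sum(v^2)), 1e-8)
})

test_that("EFG obeys translation invariance, rotation covariance and charge linearity", {
  cfg <- random_config(32, 10, 7)
  v0 <- efg_ewald(cfg, 2)[[1]]
  # rigid shift modulo the box
  shift <- c(3.1, -1.2, 0.7)
  cfg_s <- configuration(sweep(cfg$positions, 2, -shift), cfg$charges,
                         cfg$box_edge)
  expect_lt(rel_diff(efg_ewald(cfg_s, 2)[[1]], v0), 1e-9)
  # lattice-compatible 90 degree rotation about z: V -> R V R^T
  rot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  pos_r <- (cfg$positions %*% t(rot)) %% cfg$box_edge
  cfg_r <- configuration(pos_r, cfg$charges, cfg$box_edge)
  expect_lt(rel_diff(efg_ewald(cfg_r, 2)[[1]], rot %*% v0 %*% t(rot)),
            1e-9)
  # doubling all charges doubles the tensor exactly
  cfg_2q <- configuration(cfg$positions, 2 * cfg$charges, cfg$box_edge)
  expect_equal(efg_ewald(cfg_2q, 2)[[1]], 2 * v0, tolerance = 1e-12)
})

test_that("efg_series handles constant trajectories and validates spacing", {
  cfg <- random_config(16, 8, 8)
  traj <- lapply(1:3, function(i) {
    f <- cfg; f$time <- (i - 1) * 50; f
  })
  s <- efg_series(traj, probes = c(1L, 2L))
  expect_equal(dim(s$comps), c(3L, 6L, 2L))
  expect_equal(s$comps[1, , 1], s$comps[3, , 1])
  expect_equal(s$dt, 50)
  expect_gt(efg_variance(s), 0)
  traj[[3]]$time <- 137
  expect_error(efg_series(traj, 1L), "non-uniform")
})

test_that("shell decomposition is additive and respects molecule grouping", {
  # single source inside the first shell: shell tensor is the total
  cfg <- configuration(rbind(c(5, 5, 5), c(5, 5, 7)), c(0, 1), 20)
  sd1 <- shell_decompose(cfg, 1, shell_radii = c(3, 6))
  expect_equal(sd1$shells[[1]], sd1$total, tolerance = 1e-12)
  expect_equal(max(abs(sd1$remainder)), 0)
  # additivity on a random configuration
  cfg2 <- random_config(64, 12, 9)
  sd2 <- shell_decompose(cfg2, 1, shell_radii = c(2.5, 4.5))
  reconstructed <- Reduce(`+`, sd2$shells, sd2$remainder)
  expect_lt(max(abs(reconstructed - sd2$total)), 1e-10)
  expect_error(shell_decompose(cfg2, 1, c(3, 7)), "L/2")
  # a molecule straddling the boundary moves wholly with its oxygen
  pos <- rbind(c(5, 5, 5), c(5, 5, 7.9), c(5, 5, 8.4))
  cfgm <- configuration(pos, c(1, -0.8, 0.4), 20,
                        species = c("Na", "O", "H"))
  sdm <- shell_decompose(cfgm, 1, shell_radii = 3,
                         molecule = c(1L, 2L, 2L))
  # oxygen at 2.9 A pulls the hydrogen (3.4 A) into shell 1
  expect_equal(sdm$shells[[1]], sdm$total, tolerance = 1e-12)
})

test_that("shell variance converges toward the periodic total with radius", {
  lt <- gen_langevin_trajectory(toy_system_spec(n = 32, box_edge = 11,
                                               n_steps = 3000,
                                               sample_every = 30,
                                               seed = 11))
  probes <- 1:4
  radii <- c(2.5, 3.5, 4.5, 5.2)
  v_shell <- numeric(length(radii))
  v_ewald <- 0
  for (frame in lt$traj) {
    ew <- efg_ewald(frame, probes)
    for (k in seq_along(probes)) {
      dec <- shell_decompose(frame, probes[k], radii)
      v_shell <- v_shell + vapply(seq_along(radii), function(s)
        sum(Reduce(`+`, dec$shells[1:s])^2), numeric(1))
      v_ewald <- v_ewald + sum(ew[[k]]^2)
    }
  }
  dev <- abs(v_shell - v_ewald) / v_ewald
  # the first shell alone misses a sizable fraction; by r -> L/2 the
  # cumulative variance closes in on the full periodic value up to the
  # irreducible remainder of a minimal box
  expect_lt(dev[length(radii)], 0.12)
  expect_lt(dev[length(radii)], dev[1])
})

test_that("radial distribution is flat for an ideal gas and peaked for a pair", {
  traj <- lapply(1:20, function(i) {
    withr::with_seed(100 + i, {
      pos <- matrix(stats::runif(90, 0, 10), 30)
      configuration(pos, rep(0, 30), 10,
                    species = rep(c("A", "B"), 15), time = i)
    })
  })
  g <- radial_distribution(traj, "A", "B", bin_width = 0.5)
  sel <- g$r > 1 & g$r < 4.5
  expect_lt(max(abs(g$g[sel] - 1)), 0.35)
  # two fixed particles at distance 3: a single occupied bin
  traj2 <- list(configuration(rbind(c(1, 1, 1), c(4, 1, 1)), c(0, 0), 10,
                              species = c("A", "B")))
  g2 <- radial_distribution(traj2, "A", "B", bin_width = 0.25)
  expect_equal(g2$r[which(g2$g > 0)], 3, tolerance = 0.25)
  expect_equal(sum(g2$g > 0), 1L)
  expect_error(radial_distribution(traj2, "Z", "B", 0.25), "empty species")
})

test_that("coordination-conditioned variance recovers a planted ratio", {
  # two-frame toy: identical coordination -> one class with total variance
  cfg <- random_config(16, 8, 12)
  traj <- lapply(1:2, function(i) { f <- cfg; f$time <- (i - 1) * 10; f })
  s <- efg_series(traj, probes = 1L)
  vc <- variance_by_coordination(s, traj, r_shell = 3.5)
  expect_equal(nrow(vc), 1L)
  expect_equal(vc$occupancy, 1)
  expect_equal(vc$variance, efg_variance(s), tolerance = 1e-10)

  # planted class-dependent variance: class A = 0.9 x class B
  n_frames <- 4000
  base <- gen_efg_process(process_spec(1, list(list(type = "exp",
                                                    amplitude = 1,
                                                    tau = 1)),
                                       dt = 50, n_frames = n_frames,
                                       seed = 13))
  cls <- withr::with_seed(14, sample(0:1, n_frames, replace = TRUE))
  scale <- ifelse(cls == 1, 1, sqrt(0.9))
  comps <- base$comps[, , 1] * scale
  s2 <- quadrelax:::new_efg_series(comps, 50, probes = 1L)
  # trajectory with 5 or 6 neighbors inside 3 A matching the class label
  near <- c(2.0, 2.2, 2.4, 2.6, 2.8)
  traj2 <- lapply(seq_len(n_frames), function(i) {
    r <- c(near, if (cls[i] == 1) 2.9 else 3.4, 3.6)
    pos <- rbind(c(0, 0, 0), cbind(r, 0, 0))
    configuration(pos, c(1, rep(-1, 7)), 8, time = (i - 1) * 50)
  })
  vc2 <- variance_by_coordination(s2, traj2, r_shell = 3)
  expect_equal(vc2$coordination, c(5L, 6L))
  expect_equal(sum(vc2$occupancy), 1, tolerance = 1e-12)
  ratio <- vc2$variance[vc2$coordination == 5L] /
    vc2$variance[vc2$coordination == 6L]
  expect_equal(ratio, 0.9, tolerance = 0.05)
})
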