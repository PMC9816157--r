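#' Brute-force EFG at a probe site by direct lattice summation
#'
#' Sums the bare point-charge EFG
#' \eqn{V_{\alpha\beta} = \sum_i q_i (3 r_\alpha r_\beta - r^2\delta_{\alpha\beta})/r^5}
#' over all particles and a full cube of periodic images. Conditionally
#' convergent in general, but for neutral configurations the full-cube
#' truncation converges with the number of image shells and serves as the
#' independent oracle for the Ewald engine. The probe's own central-cell
#' charge is excluded; its periodic images contribute zero by cubic symmetry
#' of the complete image cube.
#'
#' @param config a [configuration].
#' @param probe particle index of the probe site (1-based).
#' @param image_shells number of image shells s; images span \{-s..s\}^3.
#' @return 3x3 symmetric traceless EFG tensor (e Angstrom^-3).
#' @export
#' @examples
#' cfg <- configuration(rbind(c(0, 0, 0), c(0, 0, 2)), c(1, 1), 20)
#' efg_direct_sum(cfg, 1, image_shells = 0)[3, 3]  # 2/2^3 * ... = 0.25
efg_direct_sum <- function(config, probe, image_shells = 6L) {
  stopifnot(inherits(config, "configuration"))
  n <- nrow(config$positions)
  if (probe < 1L || probe > n) stop("probe index out of range")
  L <- config$box_edge
  d0 <- sweep(config$positions, 2L, config$positions[probe, ])
  s <- as.integer(image_shells)
  grid <- seq.int(-s, s)
  cells <- as.matrix(expand.grid(x = grid, y = grid, z = grid)) * L
  m <- nrow(cells)
  # all source-image displacements relative to the probe
  d <- d0[rep(seq_len(n), times = m), , drop = FALSE] +
    cells[rep(seq_len(m), each = n), , drop = FALSE]
  q <- rep(config$charges, times = m)
  self <- rep(seq_len(n) == probe, times = m) & rowSums(d != 0) == 0L
  d <- d[!self, , drop = FALSE]
  q <- q[!self]
  r2 <- rowSums(d * d)
  if (any(r2 < 1e-12))
    stop("source charge within 1e-6 Angstrom of the probe site")
  bare_efg_sum(d, q, r2)
}

#' Converged direct-sum EFG by shell extrapolation
#'
#' The full-cube direct sum converges as the inverse square of the shell
#' count (the image-cell quadrupole tail). Evaluating the sum at several
#' shell counts and extrapolating the smooth tail (basis 1, s^-2, s^-3,
#' s^-4) yields the infinite-lattice limit to well below 1e-6 relative
#' without any reciprocal-space machinery, providing an oracle fully
#' independent of the Ewald engine.
#'
#' @inheritParams efg_direct_sum
#' @param shells increasing vector of image-shell counts to extrapolate over.
#' @return 3x3 EFG tensor (e Angstrom^-3).
#' @export
efg_direct_sum_converged <- function(config, probe,
                                     shells = c(6L, 8L, 10L, 12L, 14L)) {
  if (length(shells) < 3L) stop("need at least 3 shell counts")
  vs <- lapply(shells, function(s) efg_direct_sum(config, probe, s))
  x <- cbind(1, 1 / shells^2, 1 / shells^3)
  if (length(shells) >= 4L) x <- cbind(x, 1 / shells^4)
  xtx <- crossprod(x)
  v <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    y <- vapply(vs, function(m) m[i, j], numeric(1))
    v[i, j] <- solve(xtx, crossprod(x, y))[1]
  }
  (v + t(v)) / 2
}

# Bare Coulomb EFG sum over displacement rows d with charges q.
bare_efg_sum <- function(d, q, r2 = rowSums(d * d)) {
  inv_r5 <- q / (r2^2 * sqrt(r2))
  v <- matrix(0, 3, 3)
  for (a in 1:3) for (b in a:3) {
    s <- sum((3 * d[, a] * d[, b] - if (a == b) r2 else 0) * inv_r5)
    v[a, b] <- s
    v[b, a] <- s
  }
  v
}

#' Ewald summation parameters for periodic EFG evaluation
#'
#' Parameters are auto-tuned from the target relative accuracy when not
#' given: the screening parameter alpha defaults to 5.4/L, the real-space
#' cutoff to f/alpha and the reciprocal cutoff to 2 alpha f, with
#' f = sqrt(-log(accuracy)) plus a safety margin. A real-space cutoff beyond
#' L/2 is honoured by explicit image-cell expansion, so results are
#' invariant to alpha within the stated accuracy.
#'
#' @param box_edge cubic box edge L (Angstrom); used for auto-tuning.
#' @param accuracy target relative accuracy of the summation.
#' @param alpha Ewald splitting parameter (Angstrom^-1).
#' @param r_cut real-space cutoff (Angstrom).
#' @param k_max number of reciprocal shells (integer triples |n_i| <= k_max).
#' @return object of class `ewald_params`.
#' @export
ewald_params <- function(box_edge, accuracy = 1e-8, alpha = NULL,
                         r_cut = NULL, k_max = NULL) {
  if (accuracy <= 0) stop("accuracy must be positive")
  f <- sqrt(-log(accuracy)) + 0.7
  if (is.null(alpha)) alpha <- 5.4 / box_edge
  if (alpha <= 0) stop("alpha must be positive")
  if (is.null(r_cut)) r_cut <- f / alpha
  if (r_cut <= 0) stop("r_cut must be positive")
  if (is.null(k_max)) k_max <- ceiling(2 * alpha * f * box_edge / (2 * pi))
  structure(list(alpha = alpha, r_cut = r_cut, k_max = as.integer(k_max),
                 accuracy = accuracy),
            class = "ewald_params")
}

#' Periodic EFG tensors at probe sites via Ewald summation
#'
#' Full Ewald decomposition of the point-charge EFG under tinfoil
#' (conducting) boundary conditions: a complementary-error-function-screened
#' real-space sum, a Gaussian-damped reciprocal sum over second derivatives
#' of the plane-wave potential, and the isotropic self correction for the
#' probe's own compensating Gaussian. The probe charge itself is always
#' excluded. The result is symmetric and traceless to the requested
#' accuracy; residual trace is removed after verification.
#'
#' @param config a [configuration] (cubic box).
#' @param probes integer vector of probe particle indices.
#' @param params an [ewald_params]; defaults auto-tuned from the box.
#' @return list of 3x3 EFG tensors (e Angstrom^-3), one per probe.
#' @export
efg_ewald <- function(config, probes, params = ewald_params(config$box_edge)) {
  stopifnot(inherits(config, "configuration"))
  if (!inherits(params, "ewald_params")) stop("params must be ewald_params")
  L <- config$box_edge
  pos <- config$positions
  q <- config$charges
  n <- nrow(pos)
  if (any(probes < 1L | probes > n)) stop("probe index out of range")
  alpha <- params$alpha
  vol <- L^3

  # reciprocal-space structure factors, shared across probes
  kk <- seq.int(-params$k_max, params$k_max)
  kg <- as.matrix(expand.grid(x = kk, y = kk, z = kk))
  kg <- kg[rowSums(kg != 0) > 0L, , drop = FALSE] * (2 * pi / L)
  k2 <- rowSums(kg * kg)
  damp <- exp(-k2 / (4 * alpha^2)) / k2          # per k-vector
  phase <- kg %*% t(pos)                         # n_k x n
  sc <- as.vector(cos(phase) %*% q)
  ss <- as.vector(sin(phase) %*% q)

  # real-space image cells out to r_cut
  n_img <- max(0L, ceiling(params$r_cut / L - 0.5))
  ig <- seq.int(-n_img, n_img)
  cells <- as.matrix(expand.grid(x = ig, y = ig, z = ig)) * L
  m <- nrow(cells)

  lapply(probes, function(p) {
    # real space: minimum-image displacements expanded over image cells
    d0 <- sweep(pos, 2L, pos[p, ])
    d0 <- d0 - round(d0 / L) * L
    d <- d0[rep(seq_len(n), times = m), , drop = FALSE] +
      cells[rep(seq_len(m), each = n), , drop = FALSE]
    qs <- rep(q, times = m)
    r2 <- rowSums(d * d)
    self <- rep(seq_len(n) == p, times = m) & r2 < 1e-12
    keep <- !self & r2 <= params$r_cut^2
    if (any(r2[!self] < 1e-12))
      stop("source charge within 1e-6 Angstrom of the probe site")
    d <- d[keep, , drop = FALSE]
    qs <- qs[keep]
    r2 <- r2[keep]
    r <- sqrt(r2)
    erfc_ar <- pracma::erfc(alpha * r)
    gauss <- (2 * alpha / sqrt(pi)) * exp(-alpha^2 * r2)
    a_fun <- qs * (3 * erfc_ar / (r2 * r) + gauss * (3 / r2 + 2 * alpha^2))
    b_fun <- qs * (erfc_ar / (r2 * r) + gauss / r2)
    v <- matrix(0, 3, 3)
    for (a in 1:3) for (b in a:3) {
      s <- sum(d[, a] * d[, b] / r2 * a_fun) - if (a == b) sum(b_fun) else 0
      v[a, b] <- v[a, b] + s
      if (a != b) v[b, a] <- v[b, a] + s
    }

    # reciprocal space (includes the probe's Gaussian; corrected below)
    cp <- cos(phase[, p])
    sp <- sin(phase[, p])
    w <- damp * (sc * cp + ss * sp)   # sum_j q_j cos(k.(r_j - r_p)) damped
    pref <- -4 * pi / vol
    for (a in 1:3) for (b in a:3) {
      s <- pref * sum(kg[, a] * kg[, b] * w)
      v[a, b] <- v[a, b] + s
      if (a != b) v[b, a] <- v[b, a] + s
    }

    # self correction: remove the probe's own compensating Gaussian
    v <- v + diag(3) * (q[p] * 4 * alpha^3 / (3 * sqrt(pi)))

    # the exact periodic EFG is traceless; residual trace is truncation
    # error. The scale guards high-symmetry sites where the tensor itself
    # vanishes.
    fn <- max(sqrt(sum(v^2)), sum(abs(q)) / vol)
    if (fn > 0 && abs(sum(diag(v))) / fn > 1e3 * params$accuracy)
      warning(sprintf("Ewald EFG trace %.3g exceeds accuracy budget",
                      abs(sum(diag(v))) / fn))
    v <- (v + t(v)) / 2
    v - diag(3) * (sum(diag(v)) / 3)
  })
}

#' EFG time series along a trajectory
#'
#' Evaluates [efg_ewald] on every frame of a trajectory for the given
#' probes. Frames must be uniformly spaced in time.
#'
#' @param traj list of [configuration] frames with `time` metadata.
#' @param probes integer vector of probe indices (constant over frames).
#' @param params an [ewald_params]; defaults auto-tuned from the first frame.
#' @param state optional [state_point] attached to the series.
#' @return object of class `efg_series`: `comps` array of dimension
#'   (n_frames, 6, n_probes) in component order xx, yy, zz, xy, xz, yz,
#'   `times` (fs), `dt` (fs), `probes`, `params`, `state`.
#' @export
efg_series <- function(traj, probes, params = NULL, state = NULL) {
  if (length(traj) < 1L) stop("empty trajectory")
  times <- vapply(traj, function(f) f$time, numeric(1))
  if (length(times) > 1L) {
    dts <- diff(times)
    if (max(abs(dts - dts[1])) > 1e-9 * max(abs(dts), 1))
      stop("non-uniform frame spacing; resample the trajectory first")
    dt <- dts[1]
  } else dt <- NA_real_
  if (is.null(params)) params <- ewald_params(traj[[1]]$box_edge)
  comps <- array(NA_real_,
                 dim = c(length(traj), 6L, length(probes)),
                 dimnames = list(NULL, tensor_comp_names, NULL))
  for (i in seq_along(traj)) {
    tensors <- efg_ewald(traj[[i]], probes, params)
    for (j in seq_along(probes))
      comps[i, , j] <- tensor_to_comps(tensors[[j]])
  }
  new_efg_series(comps, dt, times = times, probes = probes, params = params,
                 state = state)
}

new_efg_series <- function(comps, dt, times = NULL, probes = NULL,
                           params = NULL, state = NULL, ground_truth = NULL) {
  if (length(dim(comps)) == 2L) comps <- array(comps, c(dim(comps), 1L))
  dimnames(comps) <- list(NULL, tensor_comp_names, NULL)
  if (is.null(times)) times <- (seq_len(dim(comps)[1]) - 1L) * dt
  structure(list(comps = comps, times = times, dt = dt, probes = probes,
                 params = params, state = state, ground_truth = ground_truth),
            class = "efg_series")
}

#' @export
print.efg_series <- function(x, ...) {
  d <- dim(x$comps)
  cat(sprintf("efg_series: %d frames x %d probe(s), dt = %g fs\n",
              d[1], d[3], x$dt))
  cat(sprintf("  <V_ext^2> = %.6g e^2 A^-6\n", efg_variance(x)))
  invisible(x)
}

#' Frobenius variance of an EFG series
#'
#' \eqn{\langle V^2\rangle = \langle V(0):V(0)\rangle} averaged over frames
#' and probes; the EFG processes are zero-mean by symmetry so no mean is
#' subtracted.
#'
#' @param series an `efg_series`.
#' @return scalar variance (e^2 Angstrom^-6).
#' @export
efg_variance <- function(series) {
  d <- dim(series$comps)
  tot <- 0
  for (j in seq_len(d[3]))
    tot <- tot + mean(frobenius_dot(series$comps[, , j, drop = TRUE]))
  tot / d[3]
}

#' Decompose the EFG at a probe into solvation-shell contributions
#'
#' Partitions the minimum-image direct EFG sum by radial shells around the
#' probe. The shell tensors plus the remainder reproduce the full
#' minimum-image sum exactly; the difference between that sum and the full
#' periodic (Ewald) tensor is absorbed in the remainder interpretation and
#' reported separately when `params` is given.
#'
#' @param config a [configuration].
#' @param probe probe particle index.
#' @param shell_radii increasing shell boundary radii (Angstrom), all < L/2.
#' @param molecule optional integer vector of molecule ids; when given, a
#'   whole molecule is assigned to the shell of its representative atom (its
#'   first oxygen, else its first atom), preventing split dipoles.
#' @return object of class `shell_decomposition`: list of per-shell 3x3
#'   tensors, `remainder` tensor, `total` minimum-image tensor, `radii`.
#' @export
shell_decompose <- function(config, probe, shell_radii, molecule = NULL) {
  stopifnot(inherits(config, "configuration"))
  L <- config$box_edge
  if (any(diff(shell_radii) <= 0)) stop("shell_radii must be increasing")
  if (any(shell_radii >= L / 2)) stop("shell radii must be < L/2")
  n <- nrow(config$positions)
  d <- sweep(config$positions, 2L, config$positions[probe, ])
  d <- d - round(d / L) * L
  r <- sqrt(rowSums(d * d))
  r_assign <- r
  if (!is.null(molecule)) {
    if (length(molecule) != n) stop("molecule ids must cover all particles")
    for (mid in unique(molecule)) {
      members <- which(molecule == mid)
      ox <- members[config$species[members] %in% c("O", "OW")]
      rep_atom <- if (length(ox)) ox[1] else members[1]
      r_assign[members] <- r[rep_atom]
    }
  }
  sel_base <- seq_len(n) != probe
  if (any(r[sel_base] < 1e-6)) stop("source charge on top of the probe")
  bounds <- c(0, shell_radii)
  shells <- vector("list", length(shell_radii))
  for (s in seq_along(shell_radii)) {
    sel <- sel_base & r_assign > bounds[s] & r_assign <= bounds[s + 1]
    shells[[s]] <- if (any(sel))
      bare_efg_sum(d[sel, , drop = FALSE], config$charges[sel])
    else matrix(0, 3, 3)
  }
  sel <- sel_base & r_assign > max(shell_radii)
  remainder <- if (any(sel))
    bare_efg_sum(d[sel, , drop = FALSE], config$charges[sel])
  else matrix(0, 3, 3)
  total <- Reduce(`+`, shells, remainder)
  structure(list(shells = shells, remainder = remainder, total = total,
                 radii = shell_radii),
            class = "shell_decomposition")
}

#' Radial distribution function between two species
#'
#' Minimum-image pair-distance histogram normalized by the ideal-gas
#' expectation, averaged over frames. Suggested solvation-shell boundaries
#' are the first and second local minima beyond the first peak.
#'
#' @param traj list of [configuration] frames.
#' @param center_species,partner_species species labels selecting the pairs.
#' @param bin_width histogram bin width (Angstrom).
#' @return object of class `rdf`: `r` bin centers, `g` values, and
#'   `shell_radii` (positions of the first two minima, possibly shorter).
#' @export
radial_distribution <- function(traj, center_species, partner_species,
                                bin_width = 0.1) {
  if (length(traj) < 1L) stop("empty trajectory")
  L <- traj[[1]]$box_edge
  r_max <- L / 2
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1L)
  n_pairs_tot <- 0
  for (frame in traj) {
    ci <- which(frame$species == center_species)
    pidx <- which(frame$species == partner_species)
    if (!length(ci) || !length(pidx))
      stop("empty species selection for the RDF")
    for (c0 in ci) {
      p <- setdiff(pidx, c0)
      if (!length(p)) next
      d <- sweep(frame$positions[p, , drop = FALSE], 2L,
                 frame$positions[c0, ])
      d <- d - round(d / L) * L
      r <- sqrt(rowSums(d * d))
      r <- r[r < r_max]
      counts <- counts + tabulate(findInterval(r, breaks,
                                               rightmost.closed = TRUE),
                                  nbins = length(counts))
      n_pairs_tot <- n_pairs_tot +
        length(p) / L^3   # partner density for this center
    }
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  vol_shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  g <- counts / (vol_shell * n_pairs_tot)
  shell_radii <- rdf_minima(centers, g)
  structure(list(r = centers, g = g, shell_radii = shell_radii),
            class = "rdf")
}

# first two local minima of g(r) after the first maximum (simple smoothing)
rdf_minima <- function(r, g, n_minima = 2L) {
  if (length(g) < 5L) return(numeric(0))
  gs <- stats::filter(g, rep(1 / 3, 3), sides = 2)
  gs[is.na(gs)] <- g[is.na(gs)]
  peak <- which.max(gs)
  mins <- numeric(0)
  i <- peak + 1L
  while (i < length(gs) && length(mins) < n_minima) {
    if (gs[i] <= gs[i - 1] && gs[i] < gs[i + 1]) {
      mins <- c(mins, r[i])
      # skip to the next maximum before searching again
      while (i < length(gs) && gs[i + 1] >= gs[i]) i <- i + 1L
    }
    i <- i + 1L
  }
  mins
}

#' Conditional EFG variance by first-shell coordination number
#'
#' Partitions frames by the number of partner atoms within the first-shell
#' radius of the probe and reports the conditional Frobenius variance
#' \eqn{\langle V^2 | n \rangle} and occupancy of each coordination state.
#'
#' @param series an `efg_series` (single probe used per entry of `probes`).
#' @param traj list of [configuration] frames aligned with `series` in time.
#' @param r_shell first-shell radius (Angstrom).
#' @param partner_species species counted as neighbors (default all others).
#' @return data frame with columns `coordination`, `occupancy`, `variance`,
#'   `n_frames`.
#' @export
variance_by_coordination <- function(series, traj, r_shell,
                                     partner_species = NULL) {
  d <- dim(series$comps)
  if (length(traj) != d[1])
    stop("series and trajectory must have the same number of frames")
  tt <- vapply(traj, function(f) f$time, numeric(1))
  if (any(abs(tt - series$times) > 1e-6))
    stop("series and trajectory frames are misaligned in time")
  probes <- series$probes
  coord <- matrix(0L, d[1], d[3])
  v2 <- matrix(0, d[1], d[3])
  for (i in seq_len(d[1])) {
    frame <- traj[[i]]
    L <- frame$box_edge
    for (j in seq_len(d[3])) {
      p <- probes[j]
      sel <- seq_len(nrow(frame$positions)) != p
      if (!is.null(partner_species))
        sel <- sel & frame$species %in% partner_species
      dd <- sweep(frame$positions[sel, , drop = FALSE], 2L,
                  frame$positions[p, ])
      dd <- dd - round(dd / L) * L
      coord[i, j] <- sum(rowSums(dd * dd) <= r_shell^2)
      v2[i, j] <- frobenius_dot(series$comps[i, , j])
    }
  }
  cn <- as.vector(coord)
  vv <- as.vector(v2)
  out <- do.call(rbind, lapply(sort(unique(cn)), function(k) {
    sel <- cn == k
    data.frame(coordination = k, occupancy = mean(sel),
               variance = mean(vv[sel]), n_frames = sum(sel))
  }))
  rownames(out) <- NULL
  out
}
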