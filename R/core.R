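#' Construct a periodic point-charge configuration
#'
#' A snapshot of N point charges in a cubic periodic box. Positions are
#' wrapped into \[0, L)^3 on construction; the original (possibly unwrapped)
#' coordinates are preserved in the `positions_raw` field for diffusion
#' analysis.
#'
#' @param positions N x 3 numeric matrix of coordinates (Angstrom).
#' @param charges length-N numeric vector of charges (units of e).
#' @param box_edge cubic box edge L (Angstrom).
#' @param species optional length-N character vector of species labels.
#' @param time simulation time of the frame (fs).
#' @return An object of class `configuration` with fields `positions`
#'   (wrapped), `positions_raw`, `charges`, `box_edge`, `species`, `time`,
#'   `total_charge` and logical `neutral` (|sum q| <= 1e-9 e).
#' @export
#' @examples
#' cfg <- configuration(matrix(runif(12, 0, 10), 4), c(1, -1, 1, -1), 10)
#' cfg$neutral
configuration <- function(positions, charges, box_edge,
                          species = NULL, time = 0) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (length(charges) != n) stop("length(charges) must match nrow(positions)")
  if (!is.numeric(box_edge) || length(box_edge) != 1L || box_edge <= 0)
    stop("box_edge must be a single positive number")
  if (is.null(species)) species <- rep("X", n)
  if (length(species) != n) stop("species must have one label per particle")
  total_charge <- sum(charges)
  structure(list(
    positions     = positions %% box_edge,
    positions_raw = positions,
    charges       = as.numeric(charges),
    box_edge      = box_edge,
    species       = as.character(species),
    time          = time,
    total_charge  = total_charge,
    neutral       = abs(total_charge) <= 1e-9
  ), class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: %d particles, L = %.4f A, t = %g fs\n",
              nrow(x$positions), x$box_edge, x$time))
  cat(sprintf("  total charge %.3g e (%s)\n", x$total_charge,
              if (x$neutral) "neutral" else "NOT neutral"))
  invisible(x)
}

#' Thermodynamic state point of a solution
#'
#' @param molality salt concentration c (mol/kg).
#' @param temperature absolute temperature T (K).
#' @param density optional mass density (kg/m^3).
#' @return object of class `state_point`.
#' @export
state_point <- function(molality = 0, temperature = 298.15, density = NULL) {
  if (temperature <= 0) stop("temperature must be positive")
  if (molality < 0) stop("molality must be non-negative")
  structure(list(molality = molality, temperature = temperature,
                 density = density), class = "state_point")
}

#' Bootstrap a statistic over independent samples
#'
#' Resamples with replacement over the units (typically independent
#' simulation runs) and reports the point estimate, bootstrap standard error
#' and a percentile confidence interval. Deterministic given `seed`.
#'
#' @param samples numeric vector or list of per-run statistics (length >= 2).
#' @param statistic reduction applied to a resample, default [mean].
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param conf_level confidence level of the percentile interval.
#' @param seed integer seed; all randomness is local to the call.
#' @return object of class `bootstrap_result`: `estimate`, `se`, `ci`
#'   (length 2), `conf_level`, `n_resamples`, `seed`.
#' @export
#' @examples
#' b <- bootstrap(rnorm(50), mean, n_resamples = 500, seed = 1)
#' b$se
bootstrap <- function(samples, statistic = mean, n_resamples = 1000L,
                      conf_level = 0.95, seed = 0L) {
  if (is.list(samples)) samples <- unlist(samples)
  n <- length(samples)
  if (n < 2L) stop("bootstrap needs at least 2 independent samples")
  estimate <- statistic(samples)
  local_rng(seed)
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                nrow = n_resamples)
  reps <- apply(idx, 1L, function(i) statistic(samples[i]))
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE))
  # percentile CI can miss a skewed point estimate; widen to contain it
  ci[1] <- min(ci[1], estimate)
  ci[2] <- max(ci[2], estimate)
  structure(list(estimate = estimate, se = stats::sd(reps), ci = ci,
                 conf_level = conf_level, n_resamples = n_resamples,
                 seed = seed),
            class = "bootstrap_result")
}

#' Block bootstrap over contiguous time windows of a single series
#'
#' For single-run inputs where the unit of independence is unclear, the
#' series is cut into contiguous blocks (default length chosen by the caller
#' as ~10x the slow relaxation time) which are resampled with replacement.
#'
#' @param series numeric vector (one statistic per frame).
#' @param statistic reduction applied to the concatenated resample.
#' @param block_length block length in frames.
#' @inheritParams bootstrap
#' @return `bootstrap_result`.
#' @export
block_bootstrap <- function(series, statistic = mean, block_length,
                            n_resamples = 1000L, conf_level = 0.95,
                            seed = 0L) {
  n <- length(series)
  if (block_length < 1L || block_length > n)
    stop("block_length must lie in [1, length(series)]")
  n_blocks <- floor(n / block_length)
  if (n_blocks < 2L) stop("need at least 2 complete blocks")
  blocks <- split(series[seq_len(n_blocks * block_length)],
                  rep(seq_len(n_blocks), each = block_length))
  estimate <- statistic(series)
  local_rng(seed)
  reps <- vapply(seq_len(n_resamples), function(r) {
    statistic(unlist(blocks[sample.int(n_blocks, n_blocks, replace = TRUE)],
                     use.names = FALSE))
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE))
  ci[1] <- min(ci[1], estimate)
  ci[2] <- max(ci[2], estimate)
  structure(list(estimate = estimate, se = stats::sd(reps), ci = ci,
                 conf_level = conf_level, n_resamples = n_resamples,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap: %.6g +- %.3g (%.0f%% CI [%.6g, %.6g], %d resamples)\n",
              x$estimate, x$se, 100 * x$conf_level, x$ci[1], x$ci[2],
              x$n_resamples))
  invisible(x)
}

# Seed the RNG locally: restores the caller's .Random.seed when the calling
# frame exits, so no package function leaks global random state.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  expr <- if (is.null(old))
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  else bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}
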