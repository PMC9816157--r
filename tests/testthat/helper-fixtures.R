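# Shared fixture builders; everything is generated in code.

# random neutral configuration of n particles in a cubic box
random_config <- function(n = 64L, L = 12, seed = 1L) {
  withr::with_seed(seed, {
    pos <- matrix(stats::runif(n * 3, 0, L), n)
    q <- sample(rep(c(1, -1), n / 2))
    configuration(pos, q, L,
                  species = ifelse(q > 0, "Na", "Cl"))
  })
}

# rock-salt lattice of 64 ions (cubic site symmetry -> zero EFG everywhere)
rock_salt_config <- function(a = 2, cells = 4L) {
  g <- as.matrix(expand.grid(0:(cells - 1L), 0:(cells - 1L),
                             0:(cells - 1L)))
  q <- (-1)^rowSums(g)
  configuration(g * a, q, cells * a,
                species = ifelse(q > 0, "Na", "Cl"))
}

# wrap an analytic curve as a tensor_acf for the quadrature/fit oracles
analytic_acf <- function(t, values, c0 = values[1]) {
  structure(list(lag_fs = t, value = values,
                 stderr = rep(NA_real_, length(t)),
                 n_origins = rep(1L, length(t)), c0 = c0,
                 dt = t[2] - t[1], n_probes = 1L),
            class = "tensor_acf")
}

rel_diff <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
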