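# quadrelax

Quadrupolar NMR relaxation rates of spin > 1/2 ions (typified by
²³Na⁺ in aqueous electrolytes) computed from point-charge configurations of
periodic simulation boxes, for simulators and NMR spectroscopists who want
to connect measured relaxation rates to microscopic dynamics.

Nuclei like ²³Na (spin *I* = 3/2, quadrupole moment
*Q* = 104 × 10⁻³¹ m²) relax through the coupling of their quadrupole
moment to fluctuations of the electric field gradient (EFG) tensor **V**
at the nucleus. In the extreme-narrowing regime (ω₀τ_c ≪ 1) the
longitudinal rate is

    1/T₁ = (2I+3) / (20 I² (2I−1)) · (eQ/ħ)² · ⟨V²⟩ · τ_c
         = C_Q² τ_c / 10                        (I = 3/2),

with the quadrupolar coupling constant C_Q² = (2/3)(eQ/ħ)²⟨V²⟩ and the
effective correlation time τ_c = ⟨V²⟩⁻¹ ∫₀^∞ ⟨V(0):V(t)⟩ dt.

The package provides every stage of that computation, plus the transport
analysis used to assess mechanistic relaxation models:

* **EFG engine** — full Ewald summation of point-charge EFG tensors at ion
  sites under periodic boundary conditions (`efg_ewald`, `efg_series`),
  with an independent converged direct-lattice-sum oracle
  (`efg_direct_sum_converged`), solvation-shell decompositions,
  radial distribution functions and coordination-conditioned variances.
* **Sternheimer calibration** — slope and variance-ratio estimators of the
  electron-cloud enhancement of classical EFGs against ab initio tables
  (`fit_gamma_slope`, `fit_gamma_variance`, `predict_total_variance`),
  with bootstrap errors over configurations.
* **Correlation analysis** — multi-origin tensor ACFs (FFT and direct),
  correlation times with plateau detection and fitted-tail extrapolation,
  exponential / stretched / composite fits, slow-mode fractions, and
  power-law tail diagnostics (`tensor_acf`, `correlation_time`, `fit_acf`,
  `slow_mode_fraction`, `tail_diagnostic`).
* **Relaxation assembly** — `qcc`, `quadrupolar_rate`, `narrowing_check`.
* **Transport** — Green–Kubo shear viscosity from stress ACFs, MSD
  diffusion with the Yeh–Hummer finite-size correction (ξ ≈ 2.837297,
  computed from the lattice sum by `xi_cubic`), Stokes radii, SED times
  and effective-radius fits, water dipole reorientation times, structural
  relaxation times from stretched stress-ACF tails.
* **Synthetic data** — seed-deterministic generators with attached ground
  truth: prescribed-ACF tensor processes, a toy Langevin ionic fluid,
  Maxwell-mode stress, Brownian walkers and rotors, pseudo-ab-initio EFG
  pair tables.
* **I/O** — extended XYZ with per-atom charges, CSV schemas for EFG/stress
  series, ACFs and pair tables, YAML reports, and a `run_pipeline`
  orchestrator that degrades gracefully with partial inputs.

## Worked example

A fully synthetic sodium-like study: an EFG process with the two-step
relaxation shape typical of aqueous Na⁺ (70% fast exponential at 62 fs,
30% stretched with τ_s = 1 ps, β = 0.67), external variance chosen at the
scale of classical point-charge EFGs, and the variance-ratio enhancement
factor γ′ = 12.09 applied for the electron cloud:

```r
library(quadrelax)

efg <- gen_efg_process(process_spec(
  variance = 0.0068,                       # e^2 A^-6, external EFG scale
  modes = list(list(type = "exp",       amplitude = 0.7, tau = 62),
               list(type = "stretched", amplitude = 0.3, tau = 1000,
                    beta = 0.67)),
  dt = 10, n_frames = 200000, seed = 42))

acf  <- tensor_acf(efg, max_lag = 15000)
tc   <- correlation_time(acf)
vtot <- predict_total_variance(efg_variance(efg), gamma = 12.09)
vsi  <- vtot$value * physical_constants$efg_to_si_factor^2
quadrupolar_rate(vsi, tc$tau_c * 1e-15, larmor_hz = 132.3e6)
```

```
1/T1 = 18.1748 s^-1  (C_Q = 2.008e+07 rad/s, tau_c = 4.509e-13 s, I = 1.5)
  narrowing product (omega0 = 2 pi f): 0.000375 -> extreme narrowing holds
```

The correlation time estimate (τ_c ≈ 0.45 ps) recovers the analytic value
of the planted mode mixture (0.7·62 fs + 0.3·1324 fs ≈ 441 fs) within
estimator noise, C_Q lands at the 2 × 10⁷ rad/s scale characteristic of
²³Na in water, and the resulting rate (~18 s⁻¹) is in the range measured
for aqueous NaCl. `run_pipeline()` wires the same stages together — with
Sternheimer calibration from a pair table, viscosity, diffusion,
reorientation and structural-relaxation stages — into one provenance-
stamped summary.

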