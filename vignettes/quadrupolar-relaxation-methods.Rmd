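---
title: "Computing quadrupolar NMR relaxation rates from simulated electrolytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing quadrupolar NMR relaxation rates from simulated electrolytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadrelax)
```

## The problem

Nuclei with spin $I > 1/2$, such as $^{23}$Na ($I = 3/2$), relax in NMR
experiments predominantly through the quadrupolar mechanism: the nuclear
quadrupole moment $eQ$ couples to fluctuations of the electric field
gradient (EFG) tensor $\mathbf{V}$ at the nucleus. In an electrolyte
solution those fluctuations are driven by the motion of surrounding water
molecules and ions, so the measured longitudinal rate $1/T_1$ encodes
subpicosecond collective dynamics of the liquid. `quadrelax` implements the
full chain from point-charge configurations of a periodic simulation box to
$1/T_1$, together with the transport-side quantities (viscosity, diffusion,
reorientation and structural relaxation times) needed to judge competing
mechanistic models of the relaxation.

## The model

In the extreme-narrowing regime, $\omega_0 \tau_c \ll 1$ (with $\omega_0$
the Larmor frequency and $\tau_c$ the EFG correlation time), longitudinal
and transverse rates coincide and

$$\frac{1}{T_1} \;=\; \frac{2I+3}{20\,I^2(2I-1)}
\left(\frac{eQ}{\hbar}\right)^2 \langle \mathbf{V}^2\rangle\, \tau_c ,$$

where $\langle\mathbf{V}^2\rangle = \langle \mathbf{V}(0):\mathbf{V}(0)
\rangle$ is the Frobenius variance of the EFG at the ion site and

$$\tau_c = \langle\mathbf{V}^2\rangle^{-1}
\int_0^\infty \langle \mathbf{V}(0):\mathbf{V}(t)\rangle\, dt .$$

For $I = 3/2$ the prefactor is $1/15$ and, with the quadrupolar coupling
constant defined by $C_Q^2 = \tfrac23 (eQ/\hbar)^2
\langle\mathbf{V}^2\rangle$, the rate can be recast as
$1/T_1 = C_Q^2\,\tau_c/10$ — an identity the package asserts to $10^{-12}$
relative on every result. The `narrowing_check()` helper evaluates
$\omega_0\tau_c$ under both the angular ($\omega_0 = 2\pi f$) and plain
($\omega_0 = f$) conventions rather than silently choosing one, because
both appear in the applied literature.

### Classical EFGs and the electron cloud

The EFG entering the rate is the full, all-electron field gradient. A
classical point-charge simulation yields only the external contribution
$\mathbf{V}_{\mathrm{ext}}$; the polarization of the ion's own electron
cloud enhances it by roughly an order of magnitude (the Sternheimer
antishielding effect). The package calibrates this enhancement against a
user-supplied table of matched ab initio and classical EFGs (it never
computes ab initio EFGs itself) with two estimators:

* the slope factor, $V^{\mathrm{AI}}_{\alpha\beta} =
  (1+\gamma_{\mathrm{eff}})\,V^{\mathrm{ext}}_{\alpha\beta}$, a
  least-squares fit through the origin with all six independent tensor
  components pooled (`fit_gamma_slope()`); and
* the variance-ratio factor, $(1+\gamma'_{\mathrm{eff}})^2 =
  \langle\mathbf{V}^2_{\mathrm{AI}}\rangle /
  \langle\mathbf{V}^2_{\mathrm{ext}}\rangle$ (`fit_gamma_variance()`).

When part of the ab initio EFG is uncorrelated with the point-charge EFG,
the variance ratio exceeds the slope — the correct factor for predicting
$\langle\mathbf{V}^2\rangle$ from $\langle\mathbf{V}_{\mathrm{ext}}^2\rangle$
is therefore $\gamma'$, which is what `predict_total_variance()` and the
pipeline use. Uncertainties come from bootstrap resampling over whole
configurations, respecting within-snapshot correlation between components.
The fit weights all records equally; whether off-diagonal components should
be double-weighted in the slope fit is not canonical, so the choice is
recorded in the result object (the variance-ratio estimator always uses
Frobenius weights, where off-diagonals count twice).

### Periodic EFG evaluation

`efg_ewald()` evaluates the point-charge EFG under periodic boundary
conditions by full Ewald summation with tinfoil boundary: an
erfc-screened real-space sum over image cells, a Gaussian-damped
reciprocal-space sum of plane-wave second derivatives, and the isotropic
self-correction for the probe's own compensating Gaussian. The probe's
central-cell charge is always excluded; its periodic images belong to the
lattice sum (and contribute zero at cubic-symmetric sites). Parameters
are auto-tuned from a target relative accuracy (default $10^{-8}$):
$\alpha = 5.4/L$, real cutoff $f/\alpha$ and reciprocal cutoff $2\alpha f$
with $f = \sqrt{-\ln(\mathrm{acc})} + 0.7$. When a small $\alpha$ pushes
the real cutoff beyond $L/2$, the sum expands over explicit image cells
instead of failing, which keeps results invariant to $\alpha$ (verified to
$10^{-8}$ relative in the tests).

The independent oracle, `efg_direct_sum_converged()`, uses no
reciprocal-space machinery at all: the bare lattice sum over full cubes of
images converges as $s^{-2}$ in the shell count $s$ (the cell-quadrupole
tail; dipole terms cancel between opposite cells), so evaluating at
$s = 6, 8, 10, 12, 14$ and extrapolating on the basis
$\{1, s^{-2}, s^{-3}, s^{-4}\}$ reaches the infinite-lattice limit to a few
parts in $10^{8}$. Ewald and oracle agree to $10^{-6}$ relative on every
random neutral box in the acceptance suite.

Solvation-shell decompositions (`shell_decompose()`) use the minimum-image
convention, since shells are local by construction; the remainder term
absorbs (and reports) the difference from the full periodic sum. Whole
molecules are assigned to the shell of their oxygen (or first atom) when
molecule labels are given, because splitting a water dipole across a shell
boundary makes the shell EFG converge slowly. Default shell radii come
from the first and second minima of the ion–oxygen radial distribution
function (`radial_distribution()`); explicit radii override. In a
desk-scale toy box ($L \approx 11$ Å) the cumulative shell variance
approaches the periodic total only up to an irreducible ~10% remainder —
production-sized boxes are needed for full closure, which is why the shell
test asserts the convergence trend rather than a tight end value.

### Correlation analysis

`tensor_acf()` forms the multi-origin Frobenius autocorrelation from the
six independent components (off-diagonals doubled), averaged over probes;
`fft` and `direct` estimators implement the same statistic and agree to
machine precision. No mean is subtracted: the EFG of an isotropic liquid
is zero-mean by symmetry, and estimating a mean would only add noise.

`correlation_time()` integrates the normalized ACF by trapezoid up to a
cutoff. The default cutoff detects a plateau of the running integral
(slope below $10^{-3}$ of its peak over a trailing window, 10% of the lag
range by default). On noisy sampled ACFs the pointwise criterion may never
trigger — estimator noise keeps $|C|$ above threshold — so the fallback
fits a stretched exponential to the slow tail (past the lag where
$C/C(0) < 0.2$) and cuts at 10 times the fitted mean relaxation time,
adding the fitted tail integral beyond the cutoff. Ten mean times leave an
exponential bias of order $e^{-10}$ while avoiding the extra estimator
noise a longer window would accumulate; a 20-times cutoff was tried and
only degraded the variance of Green–Kubo integrals without reducing bias.

`fit_acf()` fits the field's standard decay models to the normalized ACF
by Levenberg–Marquardt with a deterministic multi-start grid (3 starts per
decade around the 1/e crossing): a fast exponential
$a\,e^{-t/\tau_f}$, a two-exponential, a stretched (Kohlrausch)
exponential $a\,e^{-(t/\tau_s)^\beta}$, and the fast-plus-stretched
composite that matches the observed two-step relaxation of ionic EFGs
(a ~60 fs fast mode carrying ~70% of the decorrelation plus a
picosecond-scale stretched mode). The mean time of a stretched component
is $\tau\,\Gamma(1/\beta)/\beta$; `slow_mode_fraction()` reports the share
of $\tau_c$ carried by the slow mode as its amplitude-weighted mean time
over the total. That amplitude-weighted definition is one consistent
reading of "contribution of the slow relaxation process" — the
decomposition is not unique and the choice is documented here. Model
selection between two-exponential and stretched alternatives is reported
(residual norms), never automated.

`tail_diagnostic()` probes the hydrodynamic long-time tail: a log-log
slope over a window, compensated curves $t^{5/2}C(t)$ and $t^{3/2}C(t)$
scored by the variance of their detrended logarithm, and a stability flag
from the slope drift between window halves. A stretched-plus-power-law
construction in the tests shows the exponent is recoverable only after the
stretched part decays below the tail amplitude, which is exactly the
caveat that applies to real data.

### Transport and relaxation-model assessment

* `stress_acf()` symmetrizes the stress, removes the isotropic part and
  applies the conventional 1/10 prefactor; pressure offsets and
  antisymmetric components provably drop out.
* `green_kubo_viscosity()` integrates $C_{\mathrm{stress}}$ with the same
  cutoff machinery as $\tau_c$ (shared implementation, by design:
  both are Green–Kubo-type integrals).
* `msd_diffusion()` fits the multi-origin mean-squared displacement over a
  window (default 10–50% of the trajectory) and rejects non-diffusive data
  when the local log–log slope leaves $1 \pm 0.1$.
* `yeh_hummer_correct()` applies the cubic finite-size correction
  $D_\infty = D + k_B T \xi / 6\pi\eta L$; `xi_cubic()` computes
  $\xi \approx 2.837297$ from the Ewald-split lattice sum of a unit point
  charge with neutralizing background in a unit cube, with
  tolerance-driven shell counts and a convergence flag.
* `stokes_radius()`, `sed_time()` and `effective_sed_fit()` implement the
  Stokes–Einstein and Stokes–Einstein–Debye relations; the effective fit
  regresses $\tau_c$ on $\eta/k_BT$ with an intercept
  $\tau_0^{\mathrm{eff}}$ and converts the slope to an effective radius.
* `dipole_reorientation_time()` integrates the first-rank orientational
  correlation of unit vectors (for water, the HOH bisector); it computes
  the average over all supplied molecules — restricting to hydration-shell
  molecules is a caller-side selection of the input vectors.
* `structural_relaxation_time()` fits a stretched exponential to the
  stress-ACF tail past the short-time elastic part and reports
  $\tau_{\mathrm{struct}} = \tau_K\,\Gamma(1/\beta_K)/\beta_K$. The
  default window starts at the first local minimum of $|C|$ (end of the
  oscillatory part) or at the half-decay lag for monotone ACFs, whichever
  comes first — the second rule prevents the window from containing only
  estimator noise.

## Units

Internally: Angstrom, femtosecond, elementary charge, Kelvin. EFGs are
carried in $e\,\mathrm{\AA}^{-3}$ and converted to SI
($\mathrm{V\,m^{-2}}$, factor $e/4\pi\varepsilon_0 \times 10^{30}$) only
inside the rate formulas; this avoids floating-point underflow in the
tensor lattice sums. Stress is in Pascal, transport coefficients in SI.
The symbol $V$ is used in the field both for the EFG tensor and for the
box volume; the code names them `efg`/`variance` and `volume` and never
overloads one for the other.

## The synthetic-data generators

The package ships seed-deterministic generators that emit their ground
truth alongside the data, so every analysis stage can be tested as a
parameter-recovery problem:

* `gen_efg_process()` builds a stationary symmetric-traceless tensor
  process with a prescribed ACF by mapping five independent scalar
  processes onto an orthonormal traceless basis. Exponential modes use the
  exact Ornstein–Uhlenbeck recursion. Stretched modes are realized as
  finite Prony (multi-exponential) superpositions — exact stationary
  stretched processes are not Markovian — with nonnegative weights on a
  log-spaced rate grid, sum-normalized, matching the target curve to a
  recorded sup-norm tolerance (1% bound, typically ~0.1%). The default
  two-step shape (70% exponential at 62 fs plus 30% stretched at 1 ps with
  $\beta = 0.67$) mirrors the relaxation observed for sodium in aqueous
  chloride solutions.
* `gen_langevin_trajectory()` integrates soft spheres with alternating
  charges and screened minimum-image Coulomb forces by the BAOAB Langevin
  scheme, emitting wrapped configurations, unwrapped positions and virial
  stress. It is a plumbing fixture with physical structure — equipartition
  and the overdamped diffusion limit are tested — and deliberately makes
  no claim to reproduce any production force field, water model or
  thermostat.
* `gen_maxwell_stress()` (Maxwell modes, planted
  $\eta = VG\tau/k_BT$), `gen_rotational_diffusion()` (exact-norm Brownian
  rotors, planted $\tau_{\mathrm{dip}} = 1/2D_r$),
  `gen_brownian_walkers()` (exact free diffusion) and `gen_pair_table()`
  (planted Sternheimer slope with independent traceless noise, variance
  inflation exactly $\sqrt{1+\nu^2}$) cover the remaining stages.

What passing these tests shows is internal consistency and correct
estimator behavior on processes with the right correlation structure; it
does not validate any force field against experiment. Real EFG series
have non-Gaussian heterogeneity (coordination-state dependence, shell
exchange) that the Gaussian surrogate lacks; `variance_by_coordination()`
exists precisely to expose such structure in real inputs.

## Numerical choices and degenerate inputs

* Bootstrap: resampling unit is the independent run/configuration;
  single-series inputs use a block bootstrap with caller-chosen block
  length (~10 times the slow relaxation time is a sensible default).
  Resample counts (default 1000) and CI levels (95%) are configurable; no
  canonical values exist. All stochastic code takes explicit seeds and
  restores the caller's RNG state.
* Ewald: cubic boxes only; non-neutral configurations are flagged at
  construction. A source within $10^{-6}$ Å of a probe is a hard error.
* Fits: non-convergence is flagged in the result, never silent; bounds
  keep $\beta \in (0.05, 1]$ and time constants positive.
* Test problem sizes ($10^5$–$5\times10^5$ frames for recovery suites,
  64-particle boxes for Ewald equivalence) were chosen so the whole suite
  runs in minutes on one CPU while leaving each tolerance a comfortable
  margin over the measured estimator noise.

## Known limitations

* No polarizable/induced-dipole EFG terms, no smooth-particle-mesh
  acceleration (plain Ewald is adequate at these box sizes), no DFT.
* No inverse-Laplace reconstruction of the relaxation-mode distribution
  (ill-posed).
* The stretched-exponential Prony surrogate controls the ACF on sampled
  lags only; far outside the generated lag range its tail is
  multi-exponential, not stretched.
* Slow-motion (beyond-narrowing) relaxation, residual quadrupolar
  couplings and dipole–dipole contributions are out of scope.
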