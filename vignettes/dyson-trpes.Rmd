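---
title: "From CI wavefunctions to time-resolved photoelectron spectra"
author: "dysonspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CI wavefunctions to time-resolved photoelectron spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysonspec)
```

## The model

Single-photon ionization takes an n-electron molecule in a source state
$\Psi_i$ to an (n−1)-electron cation state $\Psi_\alpha$ plus a free
electron. Under the sudden approximation — the outgoing electron does not
interact with the remaining ion, and the transition dipole is treated as a
constant — the relative probability of the channel $i \to \alpha$ is
governed by the *Dyson orbital*

$$\varphi^{D}_{i\alpha}(x) \;=\; \sqrt{n}\,
  \langle \Psi_\alpha \,|\, \Psi_i \rangle_{n-1},$$

the one-electron overlap left after integrating out n−1 coordinates. Its
squared norm (the *Dyson norm*) is a cheap, surprisingly reliable proxy for
the channel's single-photon ionization yield. By analogy with the
oscillator strength of a bound–bound transition we use the amplitude

$$W_{i\alpha} \;=\; \Delta E_{i\alpha}\,\lVert\varphi^{D}_{i\alpha}\rVert^2,
  \qquad \Delta E_{i\alpha} = V_\alpha - V_i,$$

where $\Delta E$ is the binding energy of the channel. The analogue of the
f-sum rule fixes the scale: summed over a complete set of ionic states with
identical orbitals, the Dyson norms from any normalized source state add up
to the electron count. This is a structural identity of the formalism and
the package tests it exactly (`make_toy_system(complete_ion = TRUE)`).

Both states are CI expansions over Slater determinants,
$\Psi_i = \sum_a c_a \Phi_a$ and $\Psi_\alpha = \sum_b d_b \Phi_b$, in
*different* molecular-orbital sets (separate state-averaged CASSCF
calculations for the neutral and the cation are the motivating case). The
Dyson orbital is then a double sum over determinant pairs weighted by
$c_a d_b$, and each pair contribution reduces, via the annihilation
operator, to signed minors of the spin-orbital overlap matrix between the
two MO sets.

## Conventions that matter

* **Spin-orbital ordering.** Alpha block first (ascending spatial index),
  then the beta block. A determinant's normal form lists occupied indices
  strictly increasing; every annihilation phase $(-1)^{p(s)}$ counts
  preceding occupied orbitals in this ordering. Relative phases *between*
  determinant pairs change the Dyson orbital (though not single-pair
  norms), so the convention is frozen package-wide and CSF expansion,
  pair minors and the brute-force oracle all share it.
* **Spin-block factorization.** Alpha and beta orbitals never overlap, so
  each pair determinant factorizes into an alpha and a beta
  sub-determinant; removals that unbalance the per-spin electron counts
  contribute zero. The production path exploits this; the test oracle
  deliberately does not (it expands determinant overlaps as explicit signed
  permutation sums), keeping the two routes independent.
* **Minor evaluation.** Minors are LU determinants per removed orbital; no
  cofactor caching. The intended systems (tens of spin orbitals, CI
  expansions screened to a few hundred terms) do not need it.
* **Screening.** CSF-basis coefficients, determinant-basis coefficients and
  pair products $|c_a d_b|$ are screened with strict `>` against
  configurable thresholds defaulting to 1e-4. Screened expansions are *not*
  renormalized — truncation effects should be visible, not hidden; on the
  shipped toy systems the 1e-4 vs 1e-7 pair thresholds move norms by well
  under one percent. Whether screening uses $|c|$ or $c^2$ is not a settled
  convention; the package defaults to $|c|$ and exposes
  `screen = "squared"` as the alternative.
* **CSF coupling.** CSFs follow the genealogical (Yamanouchi–Kotani)
  scheme; any other convention must be converted upstream. Expansions are
  validated in the test suite as exact $\hat S^2$ eigenfunctions.

## Static spectra

`stick_spectrum()` places one stick per open channel at $\Delta E$ with
height $W$; `broaden()` convolves with a unit-area Gaussian (default FWHM
0.2 eV, the value appropriate for smoothing sparse state ladders into
band shapes); `mix_components()` averages tautomers or conformers with
abundance weights; `ensemble_spectrum()` pools Wigner-sampled geometries
with weight 1/N. Closed channels ($\Delta E < 0$, or beyond the probe
energy in the time-resolved case) are dropped, never clipped into
zero-energy bins. Two equivalent mechanisms exist for a constant
ionization-potential correction: a global shift of the binding-energy axis
(`shift` argument) or an effectively lowered probe energy in the TRPES
assembly — shifting all sticks by $-\delta$ and lowering the probe by
$\delta$ produce the same kinetic-energy positions. Per-spectrum
normalization to unit maximum is a presentation option, off by default.

The bright/dark classification used for excited-state spectra follows the
transition-dipole norm to the ground state: the larger norm is labelled
the bright (ππ\*) state, the other the dark (nπ\*) state. Near-degenerate
norms (within a relative tolerance, default 2%) are tie-broken toward the
lower state index and flagged `mixed`, because strongly mixed states make
any such label approximate.

## Wigner sampling

The vibrational ground state of a harmonic model has a Gaussian Wigner
function in every dimensionless normal coordinate and conjugate momentum,
each with variance ½. `wigner_sample()` draws both independently,
transforms coordinates back to Cartesian displacements through the
mass-weighted modes, and optionally emits momenta (harmless for static
spectra, useful for dynamics producers). Temperature is fixed at 0 K;
thermal or anharmonic sampling is out of scope. Translations and rotations
are excluded by a 10 cm$^{-1}$ wavenumber threshold (configurable); units
are Å, amu, fs and cm$^{-1}$, with $\hbar$ converted internally.

## Time-resolved assembly

A trajectory record carries, per 5 fs frame (any uniform stride works; the
default mirrors common practice of evaluating ionization properties on a
coarser grid than the nuclear propagation), the spin-mixed state weights
$w_j(t)$, state potentials, and one Dyson norm + ion potential per
channel. The instantaneous spectrum places each open channel
($\Delta E \le \hbar\omega_{\text{probe}}$) at
$E_{\text{kin}} = \hbar\omega - \Delta E$ with intensity $w_j A_{j\alpha}$.
Two intensity conventions are defensible: $A = \Delta E \cdot$ norm
(consistent with the static spectra) or the bare Dyson norm; the package
defaults to the former and exposes `mode = "norm"`, asserting neither as
canonical since the distinction is absorbed into the overall arbitrary
intensity scale whenever $\Delta E$ varies little across the window.

Ensembles mix tautomers with abundance weights (default keto:enol = 35:65,
the approximate gas-phase ratio) and normalize per time bin by the number
of trajectories still covering the bin, so trajectories of unequal length
contribute only where they exist; normalization by the total count is the
alternative (`normalization = "total"`). Mixed strides or start times are
refused rather than silently resampled.

Energy broadening (Gaussian, 0.2 eV FWHM) is applied along the energy axis
at every time bin; the pump–probe instrument response is a separate
Gaussian convolution along time (FWHM 160 fs by default in the examples,
matching a typical UV–UV cross-correlation). Boundary policy: zero before
the first frame — there is no signal before the pump — and edge-value
extension after the last frame; both configurable. The discrete kernel is
normalized to unit sum, so a time-constant signal is exactly preserved in
the interior, and the convolution of a sampled exponential matches the
closed-form exponentially-modified Gaussian to better than 1e-6 away from
the edges (the remaining difference is the half-bin quadrature offset at
the t = 0 jump).

Decomposition is attached at assembly time: by neutral state (fractional,
proportional to $w_j$), by mechanistic pathway and by tautomer (both
exclusive, from trajectory labels). Slices are stored alongside the total
and sum to it within accumulation round-off; `integrate_energy()` carries
them through to yield traces.

## Lifetime fitting

`fit_monoexponential()` fits $A e^{-t/\tau}$ by variable projection: the
amplitude is solved linearly for each candidate $\tau$, and the profiled
residual is minimized over $\log\tau$ from 8 deterministic log-spaced
starts, followed by a Levenberg–Marquardt polish that also provides the
standard error. Traces whose best $\tau$ exceeds 100× the observation span
are flagged non-decaying instead of erroring. For traces that have passed
through the time convolution, `conv_fwhm` switches the model to the
Gaussian-convolved exponential with the response width held fixed —
fitting a plain exponential to a convolved trace biases short lifetimes
toward the response width. The edge-extension region at the end of a
convolved trace can be excluded with `t_end`; by default the full range is
used, since truncation measurably worsens fits of lifetimes comparable to
the observation window.

`fit_global()` shares time constants across traces, each trace being a
linear combination of decay terms $e^{-t/\tau_k}$ and, for sequential
kinetics, rise–decay terms $e^{-t/\tau_{to}} - e^{-t/\tau_{from}}$. Which
functional form ("parallel" vs "cascade") underlies a given multi-state
data set is usually not identifiable from yields alone, so both model
specifications are available and neither is the default interpretation of
any particular system. Standard errors come from the stacked Jacobian over
(log constants, amplitudes); near-singular normal equations raise an
identifiability warning rather than fabricating errors.

## What the synthetic generator does and does not emulate

`simulate_ensemble()` produces the *structure* of a surface-hopping
post-processing problem: a bright→dark hop at an exponential hop time
(default constant 25 fs, of the order of typical ultrafast internal
conversion out of the bright state), a terminal event at an exponential
time with the pathway's lifetime, one-hot state weights, and per-state
channels whose terminal channel is closed at the probe energy — so the
ionization signal disappears after the terminal event, emulating the loss
of signal upon internal conversion to the ground state. The shipped demo
(`demo_ensemble_spec()`) uses three pathways with lifetimes 60, 250 and
1100 fs at 100 trajectories per pathway on average, 5 fs stride and
1400 fs of simulation — a multi-scale spread from tens of femtoseconds to
beyond a picosecond, which is exactly the regime where a low-component fit
of the total yield composites the pathways.

The generator deliberately does **not** emulate: geometry-dependent Dyson
norms (channels carry template values), state mixing beyond one-hot
weights (ramps would be a config extension), coordinate-dependent
energies, quartet channels, or any real molecule's surfaces. Passing the
pipeline tests therefore demonstrates correct *bookkeeping and
statistics* — weighting, gridding, convolution, decomposition, fitting —
not electronic-structure fidelity, which enters only through user-supplied
wavefunctions and trajectories.

A note on statistics: with 100 trajectories per pathway, the least-squares
lifetime estimate from a binomial survival trace has a relative sampling
standard deviation of roughly 10–16% (the noise is a correlated step
function, and lifetimes comparable to the simulation window are further
skewed by censoring). Recovery checks at the 15% level are therefore
expected to fail for an appreciable fraction of RNG seeds even with a
correct implementation; the test suite pins one seed and the
reproduction script exposes `--seed`.

## The identifiability demonstration

The package's end-to-end property is deliberately negative: generate an
ensemble from three well-separated pathway lifetimes, assemble and
convolve the TRPES, integrate the 0–4 eV kinetic-energy window, then (a)
fit each pathway's decomposed trace — each generating lifetime is
recovered — and (b) fit the *total* yield with two exponentials — the
fitted constants land between the generating ones, further from every
true lifetime than their own standard errors. A two-constant description
of a multi-pathway signal is a composite, and no amount of fit quality
makes its constants mechanistic. `scripts/acceptance.R` reproduces this
demonstration from scratch.

```{r pipeline, eval = FALSE}
spec <- demo_ensemble_spec(seed = 1)
ens  <- simulate_ensemble(spec)
grid <- assemble_trpes(ens, probe = 5.4, efwhm = 0.2,
                       tautomer_weights = c(enol = 1))
grid <- convolve_time(grid, 160)
yl   <- integrate_energy(grid, c(0, 4))
fit_monoexponential(yl$time, yl$slices$pathway[["OOP"]], conv_fwhm = 160)
fit_global(list(total = list(time = yl$time, y = yl$total)),
           n_components = 2, conv_fwhm = 160)
```

## Problem sizes and limitations

The test suite runs toy systems of 2–6 spatial orbitals and 2–4 electrons
(where the brute-force permutation oracle is exact and fast), ensembles of
30–300 trajectories, and 2000–5000 Wigner draws; these sizes make every
oracle comparison exhaustive while keeping the whole suite interactive.
Known limitations: no continuum wavefunctions, photoelectron angular
distributions, or multiphoton/strong-field yields (Dyson norms do not
describe them); orbitals within each MO set are assumed orthonormal; no
finite-temperature Wigner sampling; CSF input restricted to genealogical
coupling; trajectory resampling across strides is refused by design.
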