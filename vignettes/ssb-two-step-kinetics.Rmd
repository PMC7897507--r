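---
title: "Modelling competitive SSB binding and wrapping on long ssDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling competitive SSB binding and wrapping on long ssDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbkinetics)
```

## The system and the model

Homotetrameric single-stranded DNA binding protein (SSB) protects
transient ssDNA during replication and repair. A tetramer can hold ssDNA
in several conformations: a minimal *bound-but-unwrapped* state in which a
single OB-fold domain contacts roughly 8 nucleotides, and *wrapped* states
in which more domains engage (17 nt at moderate template tension, 35 nt at
lower tension). On a long substrate held at constant force in an optical
trap, protein binding registers as a change in end-to-end extension:
wrapping compacts the ssDNA strongly (~0.083 nm per occluded nucleotide at
12 pN), single-domain binding only weakly (~0.016 nm/nt).

`ssbkinetics` implements a mean-field two-step kinetic scheme for the
occupancy of a long lattice by such proteins. The state is the pair of
protein densities per nucleotide, `beta` (bound-unwrapped) and `omega`
(wrapped); occupancy fractions follow from the footprints,
$\Theta_b = n_b\beta$, $\Theta_w = n_w\omega$,
$\Theta_0 = 1-\Theta_b-\Theta_w$. The fluxes are

$$
\frac{d\beta}{dt} = k_b c\,\Theta_0
  - k_{\mathrm{off}}^{\mathrm{eff}}(\Theta_b)\,\beta
  - k_w\,\varphi\,\beta + k_{\mathrm{unw}}^{\mathrm{eff}}(\Theta_b)\,\omega,
\qquad
\frac{d\omega}{dt} = k_w\,\varphi\,\beta
  - k_{\mathrm{unw}}^{\mathrm{eff}}(\Theta_b)\,\omega ,
$$

with three structural choices:

* **Binding** treats every free nucleotide as a nucleation point
  (flux $k_b c \Theta_0$ in proteins·nt⁻¹·s⁻¹, no footprint
  normalisation), relying on the fast 1D diffusion of SSB on ssDNA to
  reorganise proteins after binding. This convention is what calibrates
  the model's equilibria: it reproduces the simulated critical
  concentration of ~3.4 nM and effectively saturates the substrate at
  0.1 nM free protein, as observed.
* **Wrapping** one protein consumes the extra $n_w-n_b$ nucleotides, so
  the wrapping rate carries an availability factor
  $\varphi=\min(1,\,\Theta_0/((n_w-n_b)\beta))$ that rations free ssDNA
  among wrap candidates ($\varphi=1$ when $\beta=0$). A literal
  $\varphi=\Theta_0$ variant is available
  (`parameter_set(..., availability = "linear")`) for sensitivity
  analysis; it lowers the critical concentration to ~1.9 nM.
* **Stimulation**: dissociation and unwrapping are accelerated when
  neighbouring bound-unwrapped protein can claim the released substrate,
  $k^{\mathrm{eff}} = k + k^{s}\,\Theta_b$ — linear in $\Theta_b$, the
  minimal law consistent with a rate "proportional to the
  bound-but-unwrapped fraction". Because the mechanism requires a
  wrapping-capable claimant, stimulation is active only where wrapping is
  (forces below ~15 pN and $k_w>0$); in wrap-disabled regimes release
  runs at the slow intrinsic $k_{\mathrm{off}}$, which is what the
  single-exponential ~100 s dissociation of non-wrapping complexes
  (high force, non-tetramerising mutant) shows.

Two parameter fixtures ship with the package: `table1_params()` (the
calibrated 12 pN set: $k_b$ 0.150 nM⁻¹s⁻¹, $k_{\mathrm{off}}$ 0.0171 s⁻¹,
$k_w$ 1.40 s⁻¹, stimulated scales 0.113/0.095 s⁻¹) and `prose_params()`
(the companion values 0.18/1.8/0.10/0.10 with the slow
$k_{\mathrm{off}}$ 0.017 s⁻¹). The intrinsic unwrapping rate is pinned to
0 (only an upper bound, <0.01 s⁻¹, is known); it can be overridden through
`modify_params()`. Compactions are stored as positive shortening
magnitudes.

```{r fixtures}
table1_params()
```

## Equilibria and the critical concentration

`equilibrate()` integrates to steady state (tolerance 1e-9 on the
derivatives, start-independence verified in the tests);
`steady_state()` solves the nullclines algebraically and is what
`critical_concentration()` bisects. At low concentration the wrapped
state dominates and the net compaction approaches $x_w$; increasing free
protein oversaturates the lattice, favouring the bound-unwrapped state.
The two occupancies cross at the critical concentration:

```{r critical}
p <- table1_params()
critical_concentration(p)
occupancies(equilibrate(3.4, p))
```

## Protocols, force regimes, synthetic data

`simulate_protocol()` integrates the model through a piecewise-constant
(duration, concentration, force) description with instantaneous solution
exchange (complete exchange in the flow cell takes ~1 s, far below the
phase timescales; a linear mixing ramp is available through the
`mixing_s` protocol option). Force selects the wrapped mode from a small
regime table: 35 nt / 5 nm per protein at 7 pN, 17 nt / 2 nm at 12 pN
(with the calibrated 0.083 nm/nt used at 12 pN; the geometric
2 nm/17 nt ≈ 0.118 nm/nt is kept as a cross-check only), wrapping
disabled at 15 pN and above. On entering a wrap-disabled regime wrapped
protein unwraps instantly but stays bound through one OB-fold domain —
the model has no interconversion kinetics between wrap modes, so force
changes relabel densities rather than resolving a transient. That choice
makes a 60 pN force jump decay the bound population at exactly
$k_{\mathrm{off}}$ (`force_jump_survival()`), with survivors rewrapping
on return to low force.

The synthetic-data generator reproduces the statistical structure the
fitting stage assumes: 10 Hz sampling, additive white noise
(default sigma 0.005 nm/nt) and a slow linear drift whose slope is drawn
per realization from N(0, (0.002 nm/nt per 100 s)²) — the instrument's
true figures are unpublished; these defaults keep the shortest phases
fittable while remaining clearly visible against the smallest amplitudes.
Per-trace seeds derive from the master seed through a fixed counter, so
datasets are exactly regenerable and extending a series never perturbs
existing traces. The default concentration grid spans 0.1–50 nM with
three replicates per point, mirroring the experimental design.

## Phase analysis and rate recovery

`segment_phases()` cuts a trace at the protocol boundaries and, within an
incubation, at the global compaction extremum; phases smaller than a
noise-aware threshold are discarded. `fit_exponential()` fits
$y = A e^{-k(t-t_0)} + B$ (optionally plus a linear drift term, mirroring
the instrumental drift correction), initialised from the 63%-rise time
and bounded to $k \in [10^{-4}, 100]$ s⁻¹; it is exact on noiseless
exponentials.

One identity matters when interpreting concentration-dependent rates in
this model. At low concentration every arrival (flux $k_b c \Theta_0$
per nt) is quickly wrapped, converting an $n_w$-nt footprint, so the
*extension* signal fills at rate $n_w k_b c$ — the low-concentration
slope of the apparent bind-wrap rate is $n_w k_b$, not $k_b$.
`fit_rate_curve()` therefore reports the footprint-normalised
bimolecular estimate `k_b = slope / n_w` next to the raw serial-fit
parameters (`k_b_apparent`, `k_w_apparent`). The same bookkeeping means
the high-concentration apparent rate of the slow second phase is limited
by stimulated unwrapping ($\approx k^{s}_{\mathrm{unw}}\Theta_b \approx
0.1$ s⁻¹), and the rate curve has no plateau at $k_w$: the wrapping rate
itself is not identifiable from the extension rate curve in this model,
and `k_w_apparent` should be read as a fit parameter, not a rate
estimate.

A related, deliberate limitation: with the rationed availability the
wrapped fraction approaches its equilibrium monotonically at every
concentration, so the simulated incubation is monophasic — the model
reproduces the *equilibrium* destabilisation of wrapping at high free
protein (the strongly reduced net compaction), but not a transient
wrapping overshoot. The `availability = "linear"` variant does not change
this; no variant of the scheme we examined produces both the calibrated
critical concentration and an overshoot, and we prioritise the
equilibrium calibration.

## The stochastic lattice

`run_gillespie()` simulates individual footprint-carrying proteins on a
finite lattice with exact event selection. Two modes bracket the role of
protein mobility:

* `sliding = FALSE`: strict geometry (a nucleation site needs $n_b$
  contiguous free nt; wrapping needs the extra nucleotides immediately
  adjacent, side chosen uniformly when both fit). Random filling then
  strands sub-footprint gaps — the parking-lot effect of nonspecific
  finite-footprint lattice binding — and wrapped coverage jams below 1.
* `sliding = TRUE` (default): the ideal-reorganisation limit of fast 1D
  diffusion (~300 nt²/s, making local gap equilibration much faster than
  any reaction): free nucleotides are poolable, nucleation runs at
  $k_b c$ per free nt, the total wrap propensity is rationed to
  $\min(N_{\mathrm{bound}},\, G/(n_w-n_b))$ candidates, and the gap
  configuration is re-drawn from its single-file stationary law
  (uniform stars-and-bars) after every event. This is the stochastic
  counterpart of the mean-field availability factor, and the mean of 20
  replicates at L = 8100 tracks the ODE within a few occupancy points.

Stimulation on the lattice uses the local bound-unwrapped coverage of a
±55 nt window — the distance a tetramer diffuses during one stimulated
release time, $\sqrt{300\ \mathrm{nt^2/s} \times 10\ \mathrm{s}} \approx
55$ nt — as the local version of the mean-field law. A binary
nearest-neighbour rule (`stimulation_rule = "binary"`) is available; it
saturates the enhancement at moderate densities and is deliberately not
the default. Wrap events logged at 12 pN carry the regime's 2 nm
per-protein compaction (5 nm at 7 pN), and `event_compaction_histogram()`
recovers those peaks from sparse low-concentration runs.

## RecA competition

RecA filamentation on bare ssDNA saturates exponentially
(`simulate_filamentation(coated = FALSE)`, default rate 0.1 s⁻¹, the
~10 s timescale at 100 nM RecA). On an SSB-coated substrate the filament
can only claim nucleotides the SSB releases, so the effective rate is
`min(rate_bare, release)` with a default release of 0.003 s⁻¹;
nucleation inhibition by SSB is folded into that single effective rate
rather than modelled separately, because the exponential *shape* — not
the mechanism — is the observable that distinguishes distributed from
sequential dissociation. `fit_filamentation_rate()` reports both the
exponential fit and a linear-fit R² for exactly that comparison.

## Numerical choices

* Integration: `deSolve::lsoda`, rtol 1e-8 / atol 1e-10 (1e-10/1e-12 in
  `equilibrate()`); tiny negative excursions the integrator probes are
  clamped internally, and the tests assert clamping is never material.
* Critical concentration: bisection of $\Theta_b-\Theta_w$ over
  [0.01, 1000] nM on the algebraic steady state, tolerance 1e-3 nM; a
  missing sign change raises a typed error.
* Exponential fits: `minpack.lm::nlsLM`, bounded, max 500 iterations;
  failures raise a typed error carrying the window.
* Step detection: sliding two-sample t statistic (half-window 15
  samples) with a Bonferroni-corrected threshold, step sizes from
  flanking medians; the single-event detection scheme used on the
  instrument is unpublished, so this is a standard change-point stand-in.
* Problem sizes used by the shipped tests and acceptance script — chosen
  as comfortable desk-scale settings: 300–600 s protocols at 10 Hz,
  series of 18 traces, 20 stochastic replicates at L = 8100 nt and
  100 s for the lattice/ODE comparison.

## What the synthetic data do and do not show

The generator emulates constant-force compaction traces with white noise
and slow drift on an ideal mean-field trajectory. It does not emulate
bead Brownian-motion spectra, force-feedback artefacts, flow-cell mixing
transients, Mg²⁺-dependent secondary structure, or the 17↔35 nt mode
interconversion transients a real force change might show. Passing
round-trip tests therefore demonstrates internal consistency of model,
generator and fitters — not instrument-level realism.

## Known limitations

* The mean-field incubation trace is monophasic (see above); transient
  wrapping overshoots seen in experiments at saturating protein are not
  reproduced, and phase labels `bind-unwrap`/`rebind-unwrap` only occur
  for traces that actually display those phases.
* $k_w$ is not identifiable from extension rate curves in this model
  (`k_w_apparent` is a nuisance parameter).
* Stimulated dissociation is switched off wherever wrapping is
  inaccessible; the fast transient release an oversaturated complex can
  show at 20 pN immediately after a rinse is therefore absent.
* The 56- and 65-nt wrap modes are out of scope (no tension-free
  calibration data), as are WLC/FJC polymer mechanics — extension is
  handled only as compaction in nm/nt.
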