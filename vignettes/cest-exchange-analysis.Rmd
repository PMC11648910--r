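---
title: "Multi-state exchange analysis of CEST profiles: models, fitting, and m-values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state exchange analysis of CEST profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cestfold)
```

## The problem

Sparsely populated protein conformers — folding intermediates, excited
states — are invisible in conventional NMR spectra, but they leave a
fingerprint in chemical exchange saturation transfer (CEST) experiments: a
weak radio-frequency field stepped across offsets during a saturation
period `T_EX` transfers saturation from a minor state to the observable
major-state peak whenever the RF sits at the minor state's resonance,
carving a "dip" into the intensity profile at a position given by the minor
state's chemical shift.  Globally fitting these profiles across spins and
B1 fields yields the populations and exchange rates of states as rare as a
few tenths of a percent, along with their chemical shifts.

`cestfold` implements the complete computational chain for this analysis in
the context of a four-helix-bundle domain that folds through two
intermediates: forward simulation of profiles under N-state exchange,
global fitting, residue-level chemical-shift perturbation statistics, and
urea m-value analysis of the resulting free-energy landscape.  Because raw
spectra for such systems are rarely deposited, the package also contains a
first-class synthetic-data module so that every stage is testable from
published parameters alone.

## The exchange model

An N-state network is specified by state labels (the first is the observed
major state F), fractional equilibrium populations $p_i$ ($\sum p_i = 1$),
and exchange rate constants $k_{ex,JK} = k_{JK} + k_{KJ}$ on the edges of
the topology.  Microscopic rates are never free parameters: they follow
from $k_{ex}$ and the populations through detailed balance,

$$k_{JK} = k_{ex,JK}\,\frac{p_K}{p_J + p_K}, \qquad
  k_{KJ} = k_{ex,JK}\,\frac{p_J}{p_J + p_K},$$

so that $p_J k_{JK} = p_K k_{KJ}$ holds on every edge by construction and
every cycle of the network is automatically consistent.  This matches how
such fits are reported in the literature (global $k_{ex}$ and populations,
not twelve independent rate constants) and keeps the parameterization
identifiable.

The four-state folding topology has edges F–I1, F–I2, I1–I2 and I1–U: two
folding pathways, U ⇋ I1 ⇋ F and U ⇋ I1 ⇋ I2 ⇋ F, with no direct F–U or
I2–U exchange.  The rate matrix convention is fixed package-wide as
*column acts on population*: $dp/dt = K p$ with $K_{ij} = k_{j \to i}$ for
$i \ne j$ and columns summing to zero.

```{r}
nw <- make_ff_model("four_state",
                    c(kex_FI1 = 784, kex_FI2 = 406, kex_I1I2 = 1600,
                      kex_I1U = 11000, p_I1 = 0.0027, p_I2 = 0.0083,
                      p_U = 0.0016), temperature_c = 10)
round(build_rate_matrix(nw), 2)
```

## Forward simulation

For one spin, one offset and one B1 field the evolution of
$(M_x, M_y, M_z)$ per state is governed by a $(3N{+}1)$-dimensional linear
system assembled by `evolution_matrix()`: Bloch blocks with transverse
relaxation $-R_2$, longitudinal relaxation $-R_1$, RF nutation
$\pm 2\pi B_1$ coupling $z \leftrightarrow y$ (RF phase along x; any fixed
phase yields the same $M_z$), and x–y precession at
$2\pi(\varpi_i - \Omega_{RF})$ in the RF rotating frame; exchange couples
like components of different states with the microscopic rates, and a unit
augmentation carries the $R_1 p_i$ return-to-equilibrium terms.  With this
augmented form the equilibrium magnetization is exactly stationary in the
absence of RF, a property the test suite asserts to 1e-10 and that pins
down the sign conventions.

`simulate_profile()` starts each offset from equilibrium ($M_{z,i} = p_i$),
propagates for `T_EX` by matrix exponential (compiled, Armadillo
`expmat`), reads out the major-state $M_z$ and normalizes by its
`T_EX = 0` value $p_F$.  An independent adaptive ODE integration
(\pkg{deSolve}) serves as the oracle for the propagator in the tests, with
agreement required to 1e-8.  Optional B1 inhomogeneity is modelled by
Gaussian averaging over 11 B1 values spanning ±2 SD; it is off by default
so that fits are exactly reproducible.

```{r, fig.width = 6, fig.height = 3.5}
spin <- spin_system("L55N", "15N", omega_ppm = 121.5,
                    delta_omega = c(I1 = -4, I2 = 3.5, U = -6.2))
ex <- cest_experiment(b1_hz = 52.1, tex_s = 0.4, sfrq_mhz = 700,
                      carrier_ppm = 119,
                      offsets_hz = seq(-993, 993, length.out = 201),
                      temperature_c = 10)
prof <- simulate_profile(spin, nw, ex)
plot(ex$offsets_hz / ppm_to_hz(1, "15N", 700) + 119, prof$intensities,
     type = "l", xlim = rev(range(ex$offsets_hz / 70.957 + 119)),
     xlab = "15N offset (ppm)", ylab = "I/I0")
```

The deep dip marks the F resonance; the small dip 3.5 ppm downfield is the
I2 state (0.83 % population), and the broad feature between the I1 and U
positions reflects their rapid interconversion — dips of states in fast
mutual exchange merge and shift toward the more populated partner.

## Global fitting

`fit_cest()` minimizes the error-weighted residuals over all profiles
jointly with bounded Levenberg–Marquardt (\pkg{minpack.lm}).  Sharing
structure follows standard CEST practice: kinetic parameters are global
across spins and B1 fields at one condition; each spin contributes a
signed $\Delta\varpi$ per minor state (dip positions determine the sign,
so it is fitted freely within ±15 ppm for ¹⁵N/¹³C and ±3 ppm for ¹H); R1
and R2 are per spin, shared across states, and fixed by default at their
supplied values — the synthetic truth records them, and a user fitting
real data can release them with `fix_relaxation = FALSE`.

Four-state objective surfaces are *sloppy*: some parameter combinations
(typically mixtures of the fast-exchange-pair rate, its populations, and
the slow folding rates) change the residuals by orders of magnitude less
than others, producing long, curved, nearly flat valleys with genuine
local minima.  Three design choices in `fit_cest()` address this, in
order of importance:

1. **Central-difference Jacobian** (relative step 1e-5).  Forward
   differences at the square-root-of-machine-epsilon steps most
   least-squares wrappers default to lose the sloppy Jacobian columns to
   rounding noise; the optimizer then stalls far from the optimum while
   reporting convergence.  Accurate columns let the trust-region steps
   track the valley floor.
2. **Endpoint restarts and incumbent multi-start.**  Each start reruns
   the minimizer from its own endpoint while that improves the fit by
   more than 1 % (a fresh trust region escapes stalls), and up to 5
   starts (seeded, ±15 % perturbations of the incumbent best) guard
   against local minima.  Starts stop early once a fit is essentially
   perfect (reduced chi-square < 1e-8), so clean recoveries pay for one
   start.
3. **Dip reseating.**  The one failure mode local steps can never undo is
   discrete: a spin's minor-state dip locked onto the wrong spectral
   feature (e.g., its I1 and U assignments exchanged under a merged
   dip).  Such a spin is conspicuous — its profiles fit far worse than
   everyone else's — so when one spin's residual RMS exceeds three times
   the across-spin median, its shift differences are refit alone (own
   profiles, kinetics held fixed) from 25 randomized positions spanning
   the bounds, and the global fit is repeated, keeping the result only if
   the total chi-square improves.

Tolerances are 1e-10 (function and parameter) with at most 500 iterations
per start.

Uncertainties come either from the scaled inverse of $J^TJ$ (covariance
method) or from a seeded parametric bootstrap that re-adds Gaussian noise
with the profiles' stated errors to the best-fit curves; the two agree
within a factor of ~2 on well-conditioned two-state data, and both are
exposed because published "±" values rarely state their method.  Model
levels are compared with `compare_models()` via
$AIC = \chi^2 + 2N_{free}$; note that AIC comparisons are only meaningful
when residuals are error-weighted (for noiseless, unit-weight synthetic
data $\chi^2 \approx 0$ and the parameter-count term dominates).

## Shift statistics

Fitted $\Delta\varpi$ tables are summarized per residue by the composite
statistic

$$\Delta\varpi_{RMS} = \sqrt{\frac{1}{N} \sum_{i=1}^{N}
  \left(\Delta\varpi_i / \varpi_{std,i}\right)^2},$$

where $\varpi_{std,i}$ normalizes each nucleus class by the spread of
shifts reported for it in the databases, and $N$ counts only nuclei with
an available value (glycine contributes its two Hα shifts as two terms).
The normalizer table is configuration — the package ships no silent
default, so analyses state their stds explicitly.  Residues with
$\Delta\varpi_{RMS} > 0.5$ (the conventional threshold) are classified as
structurally perturbed; `shift_rmsd()` compares shift sets between
conditions with optional residue exclusions, and `export_peaklist()`
reconstructs absolute minor-state peak positions
(minor = major + $\Delta\varpi$, the package-wide sign convention).

## Free energies and urea m-values

With populations and rates in hand at a series of urea concentrations, the
free energy of state K relative to F is
$\Delta G_{FK} = -RT\ln(p_K/p_F)$, and the transition state between K and
L is placed at
$\Delta G_{F\text{-}TS_{KL}} = -RT\ln(p_K/p_F) - RT\ln(k_{KL}/C)$ with an
arbitrary prefactor $C = 10^7\,s^{-1}$.  Detailed balance makes the
transition-state energy independent of the side it is computed from, and
changing $C$ only shifts all TS energies by a common constant — both
properties are asserted in the tests, and neither affects the m-values

$$m_J = -\,\frac{d\,\Delta G_{FJ}}{d[\text{urea}]},$$

obtained by weighted linear regression over the urea grid
(`fit_m_value()`, weights $1/SE^2$ when fit uncertainties are available,
propagated to $\Delta G$ by the delta method; unweighted otherwise).
m-values report on solvent-exposed surface area — how compact each state
and transition state is relative to F.

```{r}
sc <- cest_scenario("D")
mv <- m_value_profile(sc$urea_points)
round(sapply(mv, `[[`, "m_value"), 3)
```

## The synthetic-data module

Four scenarios pin the generator to published study conditions:

* **A** — four-state network at 10 °C, ¹⁵N CEST at B1 = 26, 52.1, 104.1,
  208.3 Hz, `T_EX` = 0.4 s, 700 MHz: $k_{ex,FI1} = 784$,
  $k_{ex,FI2} = 406$, $k_{ex,I1I2} = 1600$, $k_{ex,I1U} = 11000\,s^{-1}$,
  $p_{I1} = 0.27\,\%$, $p_{I2} = 0.83\,\%$, $p_U = 0.16\,\%$.
* **B** — two-state F/I2 exchange under glucose-stabilized conditions at
  20 °C: $k_{ex,FI2} = 587\,s^{-1}$, $p_{I2} = 2.1\,\%$, B1 = 26.4 and
  52.9 Hz.
* **C** — two-state exchange for a proline-variant condition with a
  heavily populated intermediate: $k_{ex,FI2} = 41.4\,s^{-1}$,
  $p_{I2} = 27.2\,\%$.  The B1 pair is not published for this condition;
  the package reuses the 26.4/52.9 Hz pair of the matching glucose
  experiments.
* **D** — urea series at 2.5 °C on the grid 0–1 M in 0.2 M steps:
  four-state networks constructed so that each state's
  $\Delta G_{FJ}$ varies linearly with slope $-m_J$ ($m_U = 6.6$,
  $m_{I1} = 2.8$, $m_{I2} = -0.1\ \mathrm{kJ\,mol^{-1}\,M^{-1}}$) and each
  edge's rate follows from the transition-state m-values
  ($m_{TS_{UI1}} = 4.0$, $m_{TS_{I1F}} = 2.1$, $m_{TS_{I2F}} = 0.3$;
  $m_{TS_{I1I2}} = 1.0$ is a documented placeholder with no published
  value).  The 0 M anchor free energies are taken from the Scenario A
  parameters; since the analysis extracts slopes, the anchors cancel
  exactly, which the tests confirm.

`make_spin_set()` builds seeded spin systems: the first spins are fixed
reporters with large, distinct shift differences for every minor state
(≥ 2 ppm for ¹⁵N) so all dips are identifiable, including one spin with
nearly coincident I1 and U shifts to emulate the merged dip of rapid I1/U
exchange; the rest draw uniformly from a configurable range (±8 ppm
default), with major-state shifts within ±3 ppm of the carrier.  Default
relaxation rates are R1 = 2 s⁻¹ and R2 = 20 s⁻¹ (per-state values were
not published; the truth sidecar records what was used so recovery tests
fix them knowingly).  The default offset grid is 61 points over ±14 ppm
about the carrier — wide enough to contain the largest shift differences
above.  Noise is additive Gaussian with SD expressed as a fraction of I0,
seeded, with the same SD attached as the per-point error.

### What the generator does and does not emulate

The synthetic data share the statistical structure the fitting model
assumes: exact Bloch–McConnell physics, homoscedastic Gaussian noise,
known R1/R2, ideal B1.  Passing recovery tests therefore demonstrates the
correctness and identifiability of the implementation under the published
conditions — not robustness to the artifacts of real spectrometers
(B1 miscalibration and inhomogeneity, scalar-coupling broadening of ¹³C
dips, ¹H–¹H cross relaxation, baseline distortions), none of which are
modelled.  The B1-inhomogeneity option exists for forward studies but is
off in all validation datasets.

## Numerical choices and degenerate inputs

* Matrix exponentials use scaling-and-squaring (Armadillo); the R-level
  `propagate()` goes through the same compiled kernel, and the
  matrix-assembly path (`evolution_matrix()`) is cross-checked against
  the all-compiled profile path in the tests.
* During optimization, parameter vectors whose minor populations sum to
  ≥ 1 (possible transiently under bounded LM with three populations) are
  rejected with a large residual rather than an error.
* Noiseless profiles carry no error column; residuals then use unit
  weights.  Flat, exchange-free profiles drive the minor population to
  its lower bound and flag the fit `boundary_hit`.
* Networks validate strictly positive populations summing to 1, no
  self-edges, and known state labels; `T_EX = 0` returns the initial
  magnetization exactly.
* Reduced chi-square is $\chi^2 / (N_{points} - N_{free})$; fits with
  $N_{free} \ge N_{points}$ are refused.

## Problem sizes used in validation

The recovery studies fit 10 spins at the scenario's B1 fields on the
61-point grid (2440 residuals, 37 free parameters for the four-state
case), which the multi-start optimizer completes in a few minutes on one
core.  The noisy-replicate calibration study in the test suite uses a
reduced design (4 spins × 2 B1 fields, 41-point grids, 6 replicates at 1 %
noise) — enough to check that reduced chi-square is calibrated and that
the recovered rate distribution brackets the truth, while keeping the
suite quick.

## Known limitations

* Exchange levels beyond four states, pressure/temperature-dependent
  kinetics and Eyring analysis are out of scope.
* Each condition (temperature, additive, urea point) is fitted
  independently; there is no joint fit across conditions.
* The profile model reads out the major-state z-magnetization only;
  minor-state peaks, CPMG-style dispersion, DANTE/D-CEST variants and
  multiplet structure are not modelled.
* The m-value analysis assumes a linear denaturant dependence of every
  $\Delta G$; curvature (observed for some systems over wide urea ranges)
  is not modelled.
* Topology is chosen by the user (with `compare_models()` for guidance);
  there is no automatic model selection beyond chi-square/AIC comparison
  of the provided levels.
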