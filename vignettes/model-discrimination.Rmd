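---
title: "Discriminating multi-quadruplex architectures with hydrodynamic and spectroscopic predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating multi-quadruplex architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4hydro)
```

## The problem

G-rich promoter sequences long enough to hold many G-tracts can fold, from
a single strand, into several G-quadruplex units. The 68-nt core promoter
of human telomerase reverse transcriptase (hTERT) is the motivating case:
its twelve G-tracts admit at least three qualitatively different
architectures —

* a **stacked column**: three parallel quadruplexes stacked coaxially
  into a compact 9-quartet rod;
* **beads on a string**: the same three quadruplexes connected by
  extended single-strand linkers, with no inter-quadruplex stacking;
* a **duplex–quadruplex hybrid**: two quadruplexes tethered around an
  8-bp hairpin duplex.

None of these can be distinguished by gel electrophoresis or melting
curves; they *can* be distinguished by solution-state transport
properties, because the candidates differ strongly in compactness. The
package implements the full inference chain: build an idealized atomic
model of each candidate, predict its sedimentation coefficient and
rotational relaxation time with a rigid-body bead-shell calculation,
predict the composite CD spectrum, and score the candidates against the
measured values.

## Sequence-derived properties

Molecular weights use the free-acid monomer convention,
$M = n_A\,313.21 + n_C\,289.18 + n_G\,329.21 + n_T\,304.2 - 61.96$ Da,
and extinction coefficients the nearest-neighbour method,
$\varepsilon_{260} = \sum_{\text{pairs}} \varepsilon_{NN} -
\sum_{\text{internal}} \varepsilon_{\text{mono}}$, with the
Cantor–Warshaw–Tinoco parameter set (the table the oligonucleotide
vendors use; the dinucleotide entries are dimer values, so a
dinucleotide evaluates to a single pair term). The parameter table is an
argument of `extinction260()`, so an alternative set can be swapped in.

```{r props}
oligoPropertyTable(referenceSequences())
```

## Idealized structure builders

The builders produce heavy-atom models that are volume-faithful rather
than stereochemically refined: planar G-quartets from a template with
exact 4-fold Hoogsteen geometry (N1···O6 = N2···N7 = 2.9 Å), a
sugar–phosphate cluster per nucleotide, 3.3 Å rise and 30° twist per
quartet step, 3.4 Å plane-to-plane gaps at stacking interfaces, and
5.9 Å/nt extended linkers in the unstacked model. Loops descend the
grooves on helical arcs (propeller style) or cross the terminal faces
(edgewise style, used for the antiparallel-like unit of the hybrid).
Every builder ends with a deterministic contact-relaxation pass that
pushes flexible residues radially outward until all non-bonded atoms
clear 1.5 Å, and a validity check (quartet planarity < 0.5 Å RMS, rise
within 0.1 Å, no clashes). All builders are deterministic given their
parameters.

Geometry choices worth knowing about:

* **Interface arithmetic.** Nine layers in three stacked units span
  $6 \times 3.3 + 2 \times 3.4 = 26.6$ Å of quartet planes: six
  intra-unit rises plus two interface gaps, with the gap measured
  plane-to-plane like any other stacking contact.
* **Hybrid layout.** The hairpin is folded back alongside the tethered
  quadruplex pair (24 Å plane gap between the units, hairpin axis
  offset 30 Å). A fully serial chain of quadruplex–hairpin–quadruplex
  is *less* compact than beads-on-a-string, which would invert the
  expected ordering of sedimentation coefficients; the folded layout
  reflects the intended "tethered but unstacked" architecture.
* **hTERT partition.** The 68-mer is partitioned by taking the first
  three guanines of each of its twelve G-tracts (in order) as quartet
  guanines; surplus guanines fall into loops. `htertPartitionSequence()`
  reassembles exactly the input sequence, which the tests verify.

```{r build}
st <- htertStackedModel()
st
```

## Bead-shell hydrodynamics

`shellModel()` follows the classical shell-model strategy: every heavy
atom is inflated to the hydrated **atomic element radius** (AER), the
exposed surface of the union of spheres is tiled with mini-beads of
radius $\sigma$, and the $3N \times 3N$ Rotne–Prager–Yamakawa mobility
supermatrix (with the overlap-regularized near form) is solved for the
forces that sustain each of the six rigid-body motions. Summing forces
and torques gives the $6\times6$ resistance matrix, whose inverse yields
the diffusion tensors; the translational block is referred to the
centre of diffusion. Properties are computed at three $\sigma$ values
and extrapolated linearly to $\sigma \to 0$.

Derived quantities are standard: $s = M(1-\bar v \rho)/(N_A f)$
(Svedberg), $s_{20,w}$ standardization by the
viscosity-and-buoyancy ratio, frictional ratio against an anhydrous or
hydrated reference sphere (the convention is attached to the result —
with $\bar v = 0.55$ cm³/g and $\delta = 0.3$ g/g the same measurement
gives 1.26 anhydrous and 1.09 hydrated, which brackets typical reported
values), and the rotational relaxation time
$\rho = 1/(2\bar D_r)$ from the isotropic average of the rotational
eigenvalues (the anisotropic relaxation times are exposed in the result
conditions).

Accuracy is anchored by analytic oracles in the test suite: a single
mini-bead has exactly the Stokes friction $6\pi\eta\sigma$; a sphere
tiled as a shell reproduces Stokes $D_t$ within 1 % and $D_r$ within
2 % after extrapolation; and on small bead clusters the supermatrix
solution agrees with the independent Kirkwood double-sum approximation
within 5 %.

**AER calibration.** The AER is the one genuinely free parameter of
shell-model hydrodynamics for nucleic acids and is conventionally set
by calibration against structures of known sedimentation coefficient.
`calibrateAER()` tunes it (within the physically sensible 1.5–4.5 Å)
so that a reference structure reproduces a target $s$. The package
default, `defaultAER()` = 2.67 Å, was fixed once by calibrating the
idealized stacked three-quadruplex reference model to the 4.00 S
expected for a compact 9-quartet column; it is close to the classic
2.9 Å value used for proteins. The beads-on-a-string and hybrid values
are then genuine predictions at that AER — the quantity that carries
the discrimination is the large gap between the stacked column and
both alternatives.

```{r hydro}
M <- molecularWeight(referenceSequences()["hTERT"])
h <- shellModel(st, M)
h
```

The numbers to remember: the stacked column sediments at ~4.0 S, the
unstacked and hybrid alternatives at ~3.15 and ~3.4 S — differences far
outside the ±0.04 S precision of a sedimentation velocity experiment —
and the stacked column's predicted rotational relaxation (~32 ns) is
more than twice the 14.6 ns of the equivalent anhydrous sphere
(`equivalentSphereRho0()`), as expected for a hydrated, elongated
particle.

## Fluorescence polarization (Perrin) analysis

The Perrin equation,
$(1/P - 1/3) = (1/P_0 - 1/3)(1 + 3\tau/\rho)$ with
$\rho = 3\eta V/RT$, makes $(1/P-1/3)$ linear in $T/\eta$. `perrinFit()`
is an unweighted least-squares line in that coordinate system; $P_0$
comes from the intercept and $\rho$ (reported at water/20 °C, with the
raw slope and intercept echoed so any other condition can be
recomputed) from the intercept/slope ratio. Viscosities of the
20 % sucrose buffer come from `sucroseViscosity()`, a bilinear
interpolation on a bundled table whose pure-water column holds
handbook values and whose sucrose rows come from a smooth correlation
anchored to the 20 °C relative viscosities of 10–40 % w/w sucrose.

On the convention question — the relaxation time $\rho$ (rotation
through 68.4°) and the correlation time $\phi$ (rotation through one
radian) differ by a factor 3; `correlationTime()` defaults to the
standard Debye relation $\rho = 3\phi$ and exposes the inverse
convention behind a flag, since both circulate in the polarization
literature.

**What recovery precision to expect.** The identifiability of $\rho$
depends on the lever arm $3\tau/\rho$. The generator defaults
(truth $\rho = 8.8$ ns, $\tau = 4.0$ ns — the calibration-standard
lifetime, $P_0 = 0.46$, 18 points over 5–39 °C, 2 % multiplicative
noise on $P$) describe the well-determined regime of a single compact
quadruplex: there the median relative error of $\hat\rho$ over seeded
replicates is below 5 %. For a slow tumbler like the full-length
construct ($\rho \approx 31$ ns with a nanosecond dye), the Perrin line
is shallow and the same noise level produces ~10 % errors — which is
precisely the relative uncertainty of the measured value this analysis
is meant to emulate. The pipeline reproduces the inference chain
ratio: measured 30.9 ns over predicted 14.6 ns gives an asymmetry ratio
of 2.1.

```{r perrin}
series <- genPerrin(genSpec("perrin", seed = 1))
fitResults(perrinFit(series))[c("P0", "rho_ns")]
```

## Frequency-domain lifetimes

For a multi-exponential decay, phase and modulation at angular
frequency $\omega$ follow
$S = \sum_i f_i \omega\tau_i/(1+\omega^2\tau_i^2)$,
$C = \sum_i f_i/(1+\omega^2\tau_i^2)$, phase $= \arctan(S/C)$,
modulation $= \sqrt{S^2+C^2}$. `lifetimeFit()` minimizes the joint
$\chi^2$ over both channels with the standard instrumental weights
(0.2° phase, 0.004 modulation, configurable), parameterized in log
lifetimes and a logistic fraction so the constraints
$\tau_i > 0, f_i \in (0,1), \sum f_i = 1$ hold by construction. The
4.0 ns calibration standard at 100 MHz gives the textbook check: phase
68.3°, modulation 0.370. Nearly equal lifetimes trigger an
identifiability warning rather than a silent degenerate fit.

## Synthetic data: what it does and does not show

All generators (`genPerrin`, `genLifetime`, `genCDMixture`,
`genJitterEnsemble`) are seed-deterministic and echo their ground truth
for recovery tests. Their purpose is to exercise the estimators under
the noise models the analyses assume — Gaussian noise of realistic
scale, exactly the model form being fitted. Passing tests therefore
demonstrate correctness of the estimators and the stated precision
under those assumptions; they do not probe model misspecification
(dye photophysics, scattering baselines, aggregation) present in real
measurements.

The CD components are parameterized Gaussian bands placed at the
field's landmark wavelengths (parallel: +260/−240 nm; hybrid-like:
+290 nm; duplex: weak +275/−245 nm couple); no public spectra exist
for the exact components, so absolute CD amplitudes are checked as
properties (linearity, permutation invariance, the exact 3× scaling
from 3 to 9 quartets) rather than against printed numbers.

The jitter ensemble stands in for molecular-dynamics snapshots: loop,
linker and flank atoms receive Gaussian displacements (quartet cores
and duplex stems stay rigid, matching the observation that stacking
survives long trajectories), then the same deterministic
contact-relaxation used by the builders restores excluded volume, and
snapshots that still violate the invariants — or whose chain has been
scattered beyond recognition — are redrawn, with an error if more than
half are rejected. A pure accept/reject filter is not workable here:
the idealized models pack loops only ~0.1 Å above the clash cutoff, so
at the 1 Å jitter scale every raw snapshot contains some sub-cutoff
contact. Because the relaxation only pushes outward, jittered
ensembles sediment slightly slower on average than the rigid model
(by ~0.2 S at σ = 1 Å); the ensemble is therefore used for spread, not
location.

## Model discrimination

`compareModels()` scores each candidate by
$\sum_\text{properties} |pred - obs| / \text{tol}$ and calls a
property consistent when the deviation is within tolerance. The
defaults — 0.1 S for $s_{20,w}$ (the spread of ensemble bead-shell
predictions), 4.1 ns for $\rho$ (the experimental uncertainty) — are
documented choices; no formal agreement threshold exists in this kind
of analysis, and the ranking is invariant to uniform tolerance
rescaling. Ties break deterministically by model id.
`mutantShiftReport()` summarizes mutation-induced sedimentation shifts
with a 2σ direction classification (a drop of 0.5 S at σ = 0.04 S is
"expanded").

```{r discriminate}
pred <- data.frame(model_id = c("stacked", "beads", "hybrid"),
                   s20w = c(4.00, 3.1, 3.2))
compareModels(pred, c(s20w = 4.05))
```

## Numerical choices and problem sizes

* Shell resolutions default to $\sigma$ = 2.5, 2.1, 1.8 Å with at most
  2500 beads per shell; the three hTERT-scale models then use
  800–1500 beads per resolution and a full three-model comparison runs
  in seconds on one core. The supermatrix solve uses a Cholesky
  factorization (the RPY matrix is positive definite), with a dense
  solve fallback.
* The $\sigma$-extrapolation is a linear fit over the ladder; the
  sphere oracle shows the residual bias is below 1 % (translation) and
  2 % (rotation) at these resolutions.
* Ensemble summaries in examples and checks use 4–8 snapshots; the
  spread estimate stabilizes quickly because the quartet cores are
  rigid.
* Tie-breaks and orderings are deterministic everywhere (model id in
  rankings; strand order in builders); no builder uses random numbers.

## Known limitations

* The builders are idealized: loop conformations are placed
  geometrically, not sampled from a force field, and the AER
  calibration absorbs the difference between this idealization and a
  relaxed all-atom surface. Absolute transport properties inherit the
  calibration; *differences between architectures* are the robust
  output.
* Shell tiling at these bead counts leaves the union-of-spheres
  surface slightly rough; this is shared by all models and largely
  cancels in comparisons.
* `sucroseViscosity()` is correlation-based between its anchor points
  and treats the % concentration as weight-per-weight.
* The frequency-domain fitter covers one and two components; resolving
  three or more lifetimes from 12 frequencies is rarely identifiable
  and is out of scope, as are time-domain (TCSPC) analysis and
  anisotropy decays.
* Lamm-equation inversion of raw sedimentation data is out of scope;
  the package predicts and standardizes sedimentation coefficients but
  expects measured $s$ values as inputs.
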