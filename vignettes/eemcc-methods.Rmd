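---
title: "Energy–entropy binding free energies with multiscale cell correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy–entropy binding free energies with multiscale cell correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eemcc)
```

## The model

`eemcc` computes standard binding free energies for host–guest systems with
an end-point ("energy–entropy") strategy: the Gibbs free energy of each of
four simulated systems — host in water, guest in water, host–guest complex
in water, and bulk water — is evaluated directly as $G = E - TS$ (the
pressure–volume term is omitted so that $H \approx E$), and the binding free
energy is the difference

$$\Delta G^\circ_\mathrm{bind} =
  (G_\mathrm{complex} + G_\mathrm{water}) -
  (G_\mathrm{host} + G^\circ_\mathrm{guest}).$$

The energy $E$ is the mean simulation energy; all of the method's substance
is in the entropy. Multiscale cell correlation (MCC) decomposes $S$ as a
plain sum over molecules $i$, hierarchy levels $j \in \{\text{molecule},
\text{united atom}\}$, motions $k \in \{\text{translation},
\text{rotation}\}$, and minima terms $l \in \{\text{vibrational},
\text{topographical}\}$:

$$S = \sum_i \sum_j \sum_k \sum_l S^{kl}_{ij}.$$

A united atom is one heavy atom plus its bonded hydrogens; it has three
translational degrees of freedom and 3, 2 or 0 rotational ones depending on
whether it carries more than one, exactly one, or no hydrogens
(`define_united_atoms()`).

### Vibrational terms

Vibrational entropy comes from force covariances rather than coordinate
covariances: per trajectory frame the net force on each unit is expressed
in the unit's reference frame (principal axes of inertia for a molecule,
hydrogen-bond-derived local axes for a united atom), halved in the
mean-field treatment of a unit among weakly correlated neighbours, and
weighted by $1/\sqrt{m}$; torques about the unit origin are treated the
same way with $1/\sqrt{I_a}$ weights per axis. Eigenvalues $\lambda_i$ of
the resulting covariance matrices map to frequencies

$$\nu_i = \frac{1}{2\pi}\sqrt{\frac{\lambda_i}{k_\mathrm{B} T}},$$

which are summed through the quantum-harmonic-oscillator entropy

$$S^\mathrm{vib} = k_\mathrm{B} \sum_{i=1}^{N_\mathrm{vib}}
  \left(\frac{h\nu_i/k_\mathrm{B}T}{e^{h\nu_i/k_\mathrm{B}T}-1}
  - \ln\!\left(1 - e^{-h\nu_i/k_\mathrm{B}T}\right)\right).$$

At the molecule level each motion contributes a $3\times 3$ matrix (six
modes total). United-atom translation spans all $3N$ degrees of freedom of
a molecule's $N$ united atoms, and the six lowest-frequency modes are
discarded so the count is $3N-6$ and the molecule-level rigid-body motions
are not double-counted. United-atom rotation spans the summed rotational
DOF. Rotational modes receive no such filter: the $3N-6$ count is tied
specifically to the translational duplication.

### Topographical terms

These count energy minima rather than curvature within one minimum:

* **Positional** — $S = k_\mathrm{B}\ln(1/x^\circ_\mathrm{aq})$ with the
  dilute-solute standard mole fraction $x^\circ_\mathrm{aq} = 1/55.5$
  (55.5 waters in the 1661 Å$^3$ standard volume); `positional_entropy()`.
* **Orientational (solution)** —
  $S = k_\mathrm{B}\ln(N_c^{3/2}\sqrt{\pi}\,p_\mathrm{corr}/\sigma)$,
  with the first-shell coordination number $N_c$ (a fractional trajectory
  mean), symmetry number $\sigma$, and $p_\mathrm{corr}$ = 1 for solutes,
  0.25 for water (hydrogen-bond correlation). The symbol denoting the
  divisor is read as the symmetry number throughout.
* **Orientational (bound guest)** —
  $S = k_\mathrm{B}\ln(\sigma_\mathrm{host}/\sigma_\mathrm{guest})$:
  a guest locked in the cavity samples only the host's
  symmetry-equivalent orientations (cucurbit[8]uril has $\sigma = 16$).
  The host's own positional and orientational entropy is taken as
  unchanged by binding since the host defines the reference frame.
* **Conformational** — heavy-atom dihedrals are histogrammed with 30°
  bins, each frame is assigned to its nearest circular peak
  (`assign_conformers()`), and the Gibbs–Shannon entropy
  $-k_\mathrm{B}\sum p_i \ln p_i$ is evaluated on the *joint* conformer
  distribution of all dihedrals of the molecule
  (`conformational_entropy()`); a marginal per-dihedral sum is available
  as a diagnostic upper bound. United-atom rotational topography
  (hydrogen-only dihedrals) is zero by rule: it is either symmetric
  (methyl) or strongly solvent-correlated (hydroxyl).
* **Protonation** — a guest that is half protonated unbound and fully
  protonated bound contributes $-0.5\,k_\mathrm{B}\ln 2$ on binding;
  only this case and the null case are supported, since no general
  mixture rule is defined for the method.

### Water: shells, categories, stoichiometry

Only water in the first hydration shell of the solutes is treated
explicitly; more distant water is assumed unchanged by binding. Shells are
identified with the parameter-free relative angular distance (RAD)
criterion: neighbours are accepted in order of distance unless a closer
accepted neighbour $k$ blocks candidate $j$ via
$(1/r_{ij})^2 < (1/r_{ik})^2 \cos\theta_{jik}$. Sites are water oxygens
and solute heavy atoms; a water is first-shell when a solute site survives
in its RAD set. The released-water count is fixed by the exact balance

$$N_\mathrm{WB} + N_\mathrm{WS,H\!-\!G} =
  N_\mathrm{WS,H} + N_\mathrm{WS,G},$$

with the complex's shell split between host and guest by nearest heavy
atom (ties to the host). Shell-water entropy components are pooled over
the per-frame shell population; released water takes the per-molecule
components of the bulk-water simulation, which is why the per-water WB
values are identical across guests by construction.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `temperature` | 300 | K | simulation ensemble temperature |
| `x_standard` | 1/55.5 | — | 1 M standard state in water |
| `halving` | `"halved"` | — | mean-field division of forces/torques by 2; `"raw"` recovers the physical frequency of an isolated unit |
| `frame_source` | `"self"` | — | `"complex"` evaluates a bound host's united-atom terms in the whole complex frame for consistent alignment |
| `p_corr_water` | 0.25 | — | hydrogen-bond orientational correlation |
| `bin_width` | 30 | degrees | adaptive dihedral binning resolution |
| `stride` | 1 | frames | trajectory subsampling |

The halving convention deserves a note: halving the instantaneous forces
divides every covariance eigenvalue by 4 and every frequency by 2, so
$S(\text{halved})$ equals the QHO sum evaluated at $\nu/2$. This scaling is
an exact algebraic identity (tested as such), which is why the harmonic
recovery tests run with `halving = "raw"` — that is the convention under
which an isolated oscillator's physical frequency is reproduced, while the
halved form is the method's own calibration for interacting units.

## Numerical choices

* Internal spectroscopy is done in molar SI (forces J mol⁻¹ m⁻¹, masses
  kg mol⁻¹); I/O units are Å, kJ mol⁻¹, amu, ps; reports use kcal mol⁻¹
  for free energies and J K⁻¹ mol⁻¹ for entropies.
* Principal axes are sorted by ascending moment; each axis is flipped so
  its largest-magnitude component is positive and the third axis is the
  cross product of the first two, making frames deterministic and
  right-handed.
* Covariance eigenvalues below $10^{-12}$ of the largest are treated as
  numerical nulls and excluded with a warning; an all-null matrix is an
  error, not a zero entropy.
* Means are subtracted before covariances even though mean forces vanish
  in equilibrium; on finite samples this avoids a spurious rank-one
  inflation.
* Histogram peak ties: a plateau collapses to its lowest-angle bin; a
  perfectly flat histogram yields a single peak at the lowest-angle
  maximum-count bin; frame-to-peak ties go to the lower-angle peak.
* Molecules are unwrapped across periodic boundaries (minimum image
  relative to their first atom) before any centre-of-mass, inertia or
  dihedral computation; this assumes molecules smaller than half the box.
* Forces on united atoms sum all atomic forces in the unit, including
  those on constrained hydrogens.
* Linear (collinear) molecules are rejected: all species handled here are
  treated as non-linear rigid bodies.

## What the synthetic generators emulate

`harmonic_trajectory()` samples positions and forces i.i.d. from the exact
Boltzmann distribution of independent harmonic modes along a rigid body's
principal axes, distributing net forces and torques over atoms by a
minimum-norm balance solve; its analytic entropy is
`analytic_entropy_oracle()`. The librational moments of inertia are
derived from the generated geometry (a prescribed moment inconsistent with
a real geometry would make the fixture unconstructible), and recorded with
the spec. `dihedral_fixture()` draws angles from wrapped-normal mixtures
with well separations enforced to exceed twice the bin width so the
mixture weights are the exact conformer probabilities.
`shell_fixture()` builds geometries whose first shell is known by
construction: contact waters are angularly spread beyond the mutual
blocking limit, distant waters sit directly behind them; with no contacts
the distant waters form an equidistant arc whose mutual chords ($d < D/2$)
make every arc-mate block the solute, so the true shell is empty.
`synthetic_solution()` provides a liquid-like box for integration tests
only — its forces are i.i.d. noise, not a force field.

Because sampling is static and i.i.d., passing tests demonstrate that the
estimators recover known covariances, histograms and shell memberships —
they say nothing about force-field quality, sampling convergence of real
MD, or time-correlation effects. The suite uses fixture sizes of 10⁴
frames for stochastic recoveries (tolerance 2%), ≤ 20-particle RAD
geometries, and ≤ 30-water integration boxes; these sizes make the
statistical error comfortably smaller than the asserted tolerances while
keeping the default test run fast.

## Design choices where the method leaves room

* **United-atom local axes**: $z$ along the mean heavy→H direction, $x$ in
  the plane of the first two H bonds (an arbitrary deterministic
  perpendicular for one hydrogen), $y = z \times x$.
* **Torque weighting for asymmetric united atoms** uses per-axis
  $1/\sqrt{I_a}$ about the heavy-atom origin.
* **Replicate statistics**: replicate $r$ of each of the four systems
  combines into one $\Delta G$ sample; the SEM is taken over those
  samples. Per-system error propagation is deliberately not the default
  (correlations between the four systems of one replicate would be
  ignored).
* **Solute RAD sites are heavy atoms only**; a shell water's coordination
  number counts all of its RAD neighbours, water or solute.
* **Enthalpy** uses whatever energy series the MD engine logged (total or
  potential); the difference largely cancels in the four-system
  combination and both are accepted as input.

## Known limitations

* Entropy of ions and of water beyond the first shell is neglected by
  design.
* The general protonation-mixture entropy is not implemented — only the
  published half↔full shift.
* The quasiharmonic coordinate-covariance alternative and
  mutual-information corrections are out of scope.
* Trajectory input is a documented plain-text format (plus GRO/PDB
  topologies); binary engine formats should be converted upstream.

## A worked pipeline

```{r example}
set.seed(1)
h <- harmonic_trajectory(harmonic_spec(n_frames = 2000, seed = 1))
S_meas <- vibrational_entropy(h$system, "HRM.1", "molecule", "translation",
                              halving = "raw") +
          vibrational_entropy(h$system, "HRM.1", "molecule", "rotation",
                              halving = "raw")
c(measured = S_meas, analytic = analytic_entropy_oracle(h$spec)$entropy)

bk <- water_bookkeeping(87.4, 24.3, 76.4, 2.4)
bk

tab <- cb8_reference("binding")
mae(tab$dG, tab$dG_expt)
```
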