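---
title: "Global-exchange replica sampling and free-energy landscapes: methods and design"
author: "tigerex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global-exchange replica sampling and free-energy landscapes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigerex)
```

## What this package models

`tigerex` is a desk-scale laboratory for the TIGER2 family of
replica-exchange protocols and for the conformational analysis that is
typically run on their output: dihedral PCA and inter-chain
pairwise-distance PCA, Boltzmann-inversion free-energy landscapes,
minimax barrier heights, and the projection of mutant ensembles onto
reference (wild-type) principal axes so that all constructs can be read
off one shared landscape.

Everything runs on analytic toy systems whose reference behaviour is
known in closed form or computable by brute force, so the algorithmic
content — exchange rules, shell selection, landscape construction — can
be tested quantitatively rather than eyeballed.  Units are fixed
package-wide: energies in kcal/mol, lengths in nm, temperatures in K,
angles in degrees at the user surface, with
$k_B = 0.0019872041\,$kcal mol$^{-1}$ K$^{-1}$.

## Sampling protocols

**T-REMD.** Replicas sit on a geometric ladder
$T_i = T_{\min}(T_{\max}/T_{\min})^{i/(M-1)}$.  After each sampling
phase, alternating neighbour pairs $(i, i+1)$ attempt a swap with the
standard probability
$\min\{1, \exp[(\beta_i-\beta_{i+1})(E_i-E_{i+1})]\}$.  This protocol
is asymptotically exact and serves as the package's internal reference:
on an asymmetric 1D double well its baseline ensemble reproduces the
quadrature well populations and passes a Kolmogorov–Smirnov test
against inverse-CDF samples (see the test suite).

**TIGER2 / TIGER2h / TIGER2hs.** One cycle is: sample every replica at
its rung temperature; quench all replicas to the baseline temperature;
attempt exchanges between the current baseline replica and the others
in ascending ladder order, each with
$\min\{1, e^{-(E_\mathrm{cand}-E_\mathrm{base})/k_B T_\mathrm{base}}\}$;
every accepted candidate becomes the new baseline comparator and the
displaced state is appended to the baseline ensemble (multi-acceptance);
finally the non-baseline replicas are reassigned to rungs by exchange-
energy rank (lowest energy to the lowest temperature) and reheated.
The three variants differ only in the exchange-decision energy:

* `tiger2` — the full potential energy;
* `tiger2h` — solute-only energy plus a mean-field implicit term
  (no explicit shell), the variant suited to multi-molecule systems
  whose shell size would fluctuate with binding state;
* `tiger2hs` — solute plus a *fixed-size* shell of the N nearest
  explicit solvent particles plus the implicit remainder.

The exchange energy is used only for exchange decisions, never for
propagation, so the explicit-solvent dynamics are untouched.

**Hydration-shell sizing.** N is determined once, from a pre-run
trajectory: for every frame and every solvent particle the
nearest-solute-atom distance is histogrammed in 0.005 nm bins and
N(r) is the rounded across-frame mean cumulative count at the chosen
cutoff r (rounding half to even).  Holding N fixed afterwards avoids
biasing exchange energies between states whose instantaneous shell
would differ.  The implicit remainder for the toy systems is linear in
the number of excluded particles with a per-particle constant
calibrated from the fixture (`calibrate_implicit_constant`); a GB-type
continuum model is out of scope here and the linear term exercises the
same algorithmic role.

**Propagators.** Metropolis Monte Carlo is the default within-replica
propagator: sequential single-coordinate (or single-bead) sweeps with
uniform trial moves, which keeps the algorithmic content of the cycle
while remaining cheap and exactly analysable.  A BAOAB Langevin
integrator is available for potentials exposing a gradient; after every
exchange the velocities are resampled from the Maxwell–Boltzmann
distribution at the replica's new temperature.  How velocities should
be treated at quench onset is genuinely underdetermined at the MD
level, so both "resample" and "rescale" are selectable in `quench()`.
MC step sizes are adapted per rung during the burn-in cycles toward a
30–50% acceptance rate and then frozen, so that production sampling is
a fixed, balance-preserving kernel; burn-in frames are discarded.

## Known bias of the global-exchange scheme

A point that matters for interpreting results on small systems: the
TIGER2-style exchange accepts quenched candidates with the plain
Metropolis factor but without the proposal-density correction that a
formal independence sampler would carry.  If the quench fully
equilibrates candidates at the baseline temperature, the comparator
chain's stationary distribution is proportional to $\pi(x)^2$ rather
than $\pi(x)$ — an effectively colder ensemble; if the quench is short,
candidates instead import the temperature-ladder mixture of well
weights.  On the package's asymmetric double well (barrier 2, tilt
0.8 kcal/mol, 8 rungs 280–600 K) the measured baseline population of
the favoured well is ~0.85–0.91 against 0.790 exact, and the
within-well spread is visibly narrowed, while T-REMD on the identical
infrastructure is exact.  The corresponding acceptance test records
this honestly (it fails its quadrature band); the protocol's practical
value on rugged landscapes — orders of magnitude more barrier crossings
per energy evaluation than baseline-temperature MC — is demonstrated by
a separate test.  Landscapes produced by the TIGER protocols should
therefore be read as qualitatively correct (minima and their ordering)
rather than as quantitatively exact free energies, which matches how
such landscapes are used for dimer-interface comparisons.

## Toy systems

* `make_double_well(barrier, asymmetry)` —
  $V(x) = b(x^2-1)^2 + a x/2$ on $[-2.5, 2.5]$ nm.  All population
  references come from 10⁴-point trapezoid quadrature
  (`boltzmann_quadrature`), which also provides inverse-CDF sampling.
* `make_harmonic(k, d)` — equipartition references
  ($\mathrm{var} = k_B T/k$, $\langle V \rangle = d k_B T/2$).
* `make_dihedral_chain(n, barrier, asymmetry)` — independent two-well
  torsions whose conformers separate cleanly in dPCA space.
* `make_dimer_fixture(seed, n_solvent)` — two identical 10-bead chains
  in a periodic 5 nm box, three designated interface beads per chain
  with a deep attractive cross-chain well (1.5 kcal/mol, radius
  0.47 nm), weak backbone attraction (0.05), soft-sphere solvent with
  weak mutual attraction (0.1) and a stronger solvent–interface term
  (0.2) so that first-shell versus bulk placement is energetically
  meaningful.  Pair wells are bounded (Gaussian core + Gaussian
  attraction), truncated and shifted to zero at twice the interaction
  radius.  Bonds (k = 1000 kcal/mol/nm²) and bending angles
  (k = 100 kcal/mol/rad²) are deliberately stiff relative to
  $k_B T$ so that torsion is the only soft internal degree of freedom —
  exactly the mode that backbone-dihedral restraints are meant to
  freeze during rigid-body-like docking.  The fixture starts in its
  designed bound pose (interface beads facing at the interaction
  radius), which a rigid-body grid scan confirms to be the ground
  state.

Mutations are per-bead type edits applied symmetrically to both chains
(homodimer convention); an "alanine-like" edit zeroes every well depth
of the bead, deleting its interactions without touching geometry.

## Restraints

Dihedral restraints use $E = k\,\Delta^2$ with $\Delta$ the wrapped
angular deviation in degrees and $k = 25$ kcal mol$^{-1}$ deg$^{-2}$ by
default — the printed unit of the force constant implies the
no-half-factor convention, and the $\tfrac12 k \Delta^2$ alternative is
available via a flag.  `make_rigid_body_restraints()` restrains every
internal chain dihedral at its current value, omitting a configurable
number of terminal dihedrals.  Hydrogen-bond-style restraints map to
flat-bottom distance restraints (default flat bottom 0.05 nm); whether
real backbone hydrogen-bond restraints should also constrain angles is
left open deliberately — only the donor–acceptor distance is
restrained here.

## Analysis stack

Angles enter PCA as $(\cos\theta, \sin\theta)$ pairs, which removes
the ±180° seam.  Inter-chain features are all pairwise bead–bead
distances between chain A and chain B; "normalized" is implemented as
per-feature z-scoring (the field's usual choice when unspecified;
min–max is a config option), with zero-variance features kept,
unit-scaled and flagged.  PCA is a mean-centred SVD; component signs
are fixed so the largest-magnitude loading is positive, making runs
comparable.

Landscapes are 30×30 2D histograms (the conventional resolution for
such plots) of the first two scores, converted by Boltzmann inversion
$\Delta G = -k_B T \ln(p/p_{\max})$ so the modal bin is 0; empty bins
are masked rather than pseudo-counted, since an invented floor would
fabricate barrier heights.  kT defaults to the 280 K baseline
temperature.  Barriers between bins are minimax path costs over
8-connected unmasked bins (widest-path Dijkstra), checked in the tests
against exhaustive path enumeration on small grids and an exact
threshold-connectivity oracle on larger ones.

Mutant ensembles are projected with the *wild-type* feature
normalization, mean and components, and binned on the wild-type grid —
without this, "the same landscape" would be meaningless.  The A/B
chain labelling is taken from the topology; automatic A↔B
symmetrization of the homodimer features is off by default (a flagged
choice, since nothing forces either convention).

## Reproducibility and numerical choices

Every run draws all randomness from one master seed: each replica owns
a private RNG stream, the exchange scheduler another, all derived
deterministically (`derive_seed`).  Runs are bit-reproducible; the
mutant-panel workflow runs every construct with the same seed policy so
an identity edit reproduces the wild type bit for bit.  Ties in the
exchange rule ($\Delta E = 0$) accept with probability 1 (Metropolis
convention); ties in energy-rank reassignment break by previous rung
index; shell-selection ties break by particle index.  Proposals outside
a potential's declared domain are rejected; a non-finite energy aborts
with a diagnostic rather than silently corrupting the chain.

## Problem sizes used by the tests and the acceptance script

Chosen as the smallest sizes at which the statistical checks have
clear margins: 1D protocol runs use 8 rungs over 280–600 K with 20
sampling / 10 quench sweeps per cycle and 1 500–2 250 recorded cycles;
the solvated reduction check uses the 200-particle fixture for a few
cycles (the property is exact, not statistical); the docking panel
uses the vacuum dimer on 4 rungs over 280–450 K, 15/8 sweeps and 150
cycles per construct; closed-form Monte Carlo checks use 10⁴–10⁵
draws.  The two-basin recovery uses 10⁵ frames, where the designed
1.0 kcal/mol gap is recovered to within a few hundredths.

## What the toy fixtures do and do not show

The generator reproduces the *algorithmic* circumstances of zinc-finger
dimer sampling — a bound interface stabilised by a few hydrophobic-like
contacts, explicit solvent with a meaningful first shell, rigid-body
docking under dihedral restraints, mutants as interaction edits — with
analytically checkable references.  It does not emulate all-atom force
fields, electrostatics, real hydration structure, or the conformational
entropy of side chains; passing tests demonstrate that the sampling and
analysis machinery is implemented correctly, not that any particular
biological system is well described.  The documented cold bias of the
global-exchange scheme is the main caveat when reading absolute free
energies off TIGER-generated landscapes.
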