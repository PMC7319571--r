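---
title: "Empirical partial atomic charges: models, parameters and large-molecule solvers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical partial atomic charges: models, parameters and large-molecule solvers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atomcharge)
```

## The problem

Partial atomic charges assign one real number per atom as a compact model
of a molecule's charge-density distribution.  They are not observables --
different charge models legitimately disagree -- but they drive a large
share of everyday molecular reasoning: electrostatics in docking and
molecular dynamics, QSAR descriptors, pKa estimation, binding-site
analysis.  Quantum-chemical charges are accurate but expensive;
*empirical* schemes compute charges in milliseconds from tabulated atomic
parameters plus the molecular topology or geometry, which keeps them
usable on drug libraries and whole proteins.

This package implements the two families that dominate practice, behind
one front door (`calculate_charges()`), one parameter-set registry, and
solvers that scale to macromolecules.

## Conformationally independent (2D) methods

These see only the bond graph.

**PEOE** (partial equalization of orbital electronegativity).  Each atom
has a charge-dependent electronegativity
$\chi_i(q) = a_i + b_i q_i + c_i q_i^2$ with published polynomial
coefficients per element and hybridisation.  In damped cycles
$k = 1, 2, \dots$ every bond transfers

$$\Delta q = \frac{\chi_{hi} - \chi_{lo}}{\chi^+_{lo}}\left(\tfrac12\right)^k$$

of positive charge to its less electronegative end, where $\chi^+$ is
the cation electronegativity $a+b+c$ of that end (20.02 for hydrogen, a
constant of the original scheme).  Transfers are pairwise antisymmetric,
so $\sum q_i$ is conserved exactly.  Defaults: tolerance $10^{-6}$ e on
the per-cycle change, at most 100 cycles (the damping makes convergence
geometric; the original scheme's fixed six cycles are subsumed).  Our
implementation agrees with the RDKit Gasteiger implementation to a few
$10^{-5}$ e on identical inputs.

**MGC.**  Sanderson-style geometric-mean equalization per connected
component: the molecular electronegativity is the geometric mean of the
atomic (Pauling-scale) values and an atom's raw charge is its deviation,
normalized by the Sanderson charge-response scale $2.08\sqrt{\chi_i}$;
the total-charge residual is spread uniformly (a uniform shift cannot
split a symmetry orbit).  With the classical Sanderson table the
normalization constant matches that scale's units; we tabulate Pauling
values, so MGC charges should be read comparatively, not absolutely.

**VEEM.**  Parameter-free bond-pair splitting: a bond of order $m$
between atoms with valence-electron counts $v_i, v_j$ shifts
$m\,(v_j - v_i)/(v_i + v_j)$ positive charge toward the
electron-poorer atom.  Formal charges remain as a baseline, which makes
$\sum q = Q$ exact.

**Del Re.**  The classical inductive scheme: solve
$\delta_i = \delta^0_i + \sum_{j \sim i} \gamma_{ij}\,\delta_j$ over the
bond graph, then convert each bond to a transfer
$q_{ij} = (\delta_j - \delta_i) / (2\varepsilon_{ij})$.  Disconnected
components are solved independently.  The bundled Del Re set is
synthetic (plausible magnitudes, clearly labelled); supply a fitted set
for production use.

## Conformationally dependent (3D) methods

EEM, SFKEEM, QEq, EQeq and EQeq+C share the electronegativity
equalization principle: at equilibrium every atom's effective
electronegativity equals one molecular value $\bar\chi$.  With a linear
atomic model this is the $(N{+}1)$-unknown linear system

$$A_i + B_i q_i + \sum_{j \ne i} k(i, j, R_{ij})\, q_j = \bar\chi,
\qquad \sum_i q_i = Q,$$

which we keep in exactly that form (the constraint row `(1, ..., 1, 0)`
and a $-1$ column for $\bar\chi$); eliminating $\bar\chi$ symmetrically
would save nothing and obscures the certificate check below.  The
methods differ only in the kernel $k$:

| method | diagonal | off-diagonal | right side |
|---|---|---|---|
| EEM    | $B_i$   | $\kappa / R_{ij}$ | $-A_i$ |
| SFKEEM | $2B_i$  | $2\sqrt{B_iB_j}\,\mathrm{sech}(\sigma R_{ij})$ | $-A_i$ |
| QEq    | $J_i$   | $k_e\,\mathrm{erf}\!\big(R/\sqrt{2(r_i^2+r_j^2)}\big)/R$ | $-\chi_i$ |
| EQeq   | $J_i$   | $\lambda k_e\big[\tfrac1R + e^{-(aR)^2}(\tfrac{2a}{\sqrt\pi} - a^2R - \tfrac1R)\big]$, $a = \sqrt{J_iJ_j}/k_e$ | $-\chi_i$ |

with $k_e = 14.399645$ eV Å/e².  Units: electronegativity-like slots in
eV, hardness-like slots in eV/e, lengths in Å (inputs are in Å in all
supported formats, so nothing is converted).  The QEq off-diagonal is
the Coulomb integral of two spherical Gaussian charge clouds whose
widths are the tabulated screening radii; the EQeq form is an
orbital-overlap-screened Coulomb.  Both tend to the bare $k_e/R$ tail at
separation and stay finite at contact.

**QEq hydrogen self-consistency.**  Hydrogen's hardness depends on its
charge; we use $J_H(q) = J_H^0\,(1 + q_H)$, clamped below at
$0.1\,J_H^0$, and resolve the system in a damped fixed-point loop
(mixing 0.5, tolerance $10^{-6}$ e, at most 50 iterations).  On
convergence the *exact* solution of the final linear system is returned,
so the equalization certificate holds to solver precision with the
recorded effective diagonal.  Molecules without hydrogen converge in a
single pass.

**EQeq+C** adds an additive bond correction: each bond moves its
tabulated correction `c` from its second atom to its first (as ordered
in the stored bond key), preserving $\sum q$ by construction; with all
corrections zero it reduces to EQeq exactly.  **GDAC** is a PEOE-style
iteration whose per-bond damping depends on geometry,
$f_{ij} = 0.5\,(r^{cov}_i + r^{cov}_j)/R_{ij}$ clamped to
$[0.05, 0.95]$: compressed bonds equalize more strongly.

**Certificate.**  For every equalization method the package can
recompute each atom's effective electronegativity from the returned
charges; the spread around $\bar\chi$ is below $10^{-6}$ eV in the test
suite.  Degenerate geometry ($R_{ij} < 10^{-4}$ Å) is a hard error, not
a silent regularization; ill-conditioned systems (reciprocal condition
below $10^{-12}$) are rejected with a structured error.

## Parameter sets and automatic selection

Parameter sets live as versioned JSON files keyed by
(element, classifier scheme, classifier value).  Three schemes cover the
published sets: `plain` (element only), `hbo` (highest incident bond
order; an isolated atom is "1" so monoatomic ions stay parameterizable)
and `hyb` (sp/sp2/sp3 from bond orders).  Bundled sets transcribe
published tables -- Geidl 2015 EEM (hbo-typed, drug-like calibrations),
Bultinck 2002 EEM, Rappé--Goddard 1991 QEq, Gasteiger--Marsili 1980
PEOE, and EQeq/GDAC slots from experimental ionization energies and
electron affinities -- each file carrying its citation.  Two bundled
sets (SFKEEM, Del Re) are labelled synthetic because the fitted
originals were not available for transcription.

A method is *applicable* to a molecule when every atom type (and, for
Del Re, every bond type) has an entry; methods without per-element
parameters are applicable to everything.  Automatic selection restricts
to methods applicable to **all** input molecules, prefers 3D methods in
the order EEM, SFKEEM, QEq, EQeq, EQeq+C, GDAC when all molecules carry
coordinates (2D order: PEOE, MGC, DelRe, VEEM), and among covering sets
picks the one with the fewest surplus atom types, breaking ties by
registry order.  EEM leads the order because it is the method of record
for the package's worked examples, and the drug-like Geidl sets lead the
registry because, among the bundled candidates, the HF/AIM calibration
reproduces the package's phenol reference values most closely (its
B3LYP/AIM sibling is a close second).  One batch never mixes parameter
sets: charges computed under different sets are not comparable.

## Large molecules: cutoff and cover

A dense equalization solve is $O(N^3)$; beyond roughly 20 000 atoms it
stops being interactive.  The package routes automatically: full solve
up to 20 000 atoms, *cutoff* above that, *cover* from 80 000 atoms
(both bounds overridable).

The cutoff strategy solves, for every atom, the local equalization
subsystem over its neighbors within a radius (default 12 Å, a typical
electrostatics cutoff) and keeps only the center's charge; the cover
strategy solves one such system per center of a greedy half-radius
cover and reads whole groups of charges from their nearest center's
solve.  Neighbor lists come from a uniform spatial grid and are exact.

The textbook version of this scheme prescribes each local subsystem's
total charge as the sum of its atoms' formal charges.  We found that
this single-pass convention converges noisily: forcing formal-charge
neutrality onto windows that overlap genuinely polarized regions (chain
ends above all) leaves errors that fluctuate rather than shrink as the
radius grows.  Both strategies therefore iterate: refinement passes
re-solve every window with (i) its total charge taken from the previous
pass and (ii) the external potential of the previous pass's charges
within three radii added to the right-hand side.  The iteration is
over-relaxed (factor 1.5, with a guard that drops to plain iteration if
an update grows) and stops when no charge moves by more than
$5\times10^{-5}$ e, after at most 150 passes.  Every pass ends with the
uniform additive correction that makes $\sum q = Q$ exact.  Cost stays
linear in $N$ at fixed radius; with a radius at least the molecular
diameter every window is the full system and the dense solution is
reproduced to $10^{-10}$.

## Synthetic fixtures and what the tests show

`make_fixture()` builds deterministic molecules -- exactly symmetric
methane and diatomics, a phenol-like ring, chains, helices and seeded
random polymers (a private Lehmer stream; the global RNG is never
touched) -- and `make_toy_parameters()` builds full-coverage parameter
sets with hardness slots bounded away from zero.  The test suite runs
every method over these combinations and asserts conservation
($|\sum q - Q| < 10^{-8}$), equal charges on topological symmetry
orbits, permutation equivariance, rigid-motion invariance and the
equalization certificate, plus agreement of the production solver with
a naive Gaussian-elimination oracle to $10^{-10}$ on small random
systems.

Solver-convergence studies use a 1000-atom helix (2.3 Å radius, 0.5 Å
rise and 100° turn per atom -- a dense, protein-like packing) of
uniform carbon with a single mid-chain oxygen substitution.  The probe
is deliberate: a uniform composition has exactly zero charges (nothing
polarizes), and a fully disordered composition makes the sup-norm error
a maximum over hundreds of noisy, near-tied contributions that
fluctuates between radii; one substitution gives the error a single
dominant source -- the truncated polarization cloud around the defect --
whose magnitude decays smoothly and monotonically as the radius grows.
The cover scan additionally holds the covering spacing fixed at 3 Å so
that growing the radius enlarges the windows around a fixed cover
geometry; coupling the spacing to the radius (the production default)
moves the centers between scan points and adds center-placement jitter
to the error.  Refinement runs at a tightened tolerance (1e-7 e) in
these studies so iteration residue stays far below the truncation error
being measured.  The scaling check compares 1000- against 4000-atom
chains at a fixed 6 Å radius and asserts subquadratic growth.  These fixtures
emulate size, composition and connectivity, not chemistry: passing them
shows the solvers and invariants are right, not that any parameter set
is accurate for real molecules -- that burden lies with the published
calibrations the registry transcribes.

The seven phenol reference structures under `inst/extdata/phenols/` are
synthetic conformers regenerated from SMILES (Open Babel `--gen3d`),
not database geometries; per-atom charges on them reproduce the
published reference values to about 0.01 e, and the perfect negative
rank correlation between pKa and the phenolic hydrogen's EEM charge is
geometry-robust and asserted exactly.

## Known limitations

- Aromaticity is not perceived; kekulized input orders are used as
  given (MOL2 `ar` bonds count as order 2 for typing).  Protonation
  states and tautomers are taken as supplied, and missing hydrogens are
  never added (polymer inputs without hydrogen trigger a warning).
- MGC and VEEM are classical closed forms on physicochemical tables;
  they are meant for ordering and quick screening, not for quantitative
  electrostatics.
- The bundled SFKEEM and Del Re sets are synthetic demonstrations.
- mmCIF reading keeps the first model and the highest-occupancy
  alternate locations; chemical-component dictionaries are not
  consulted.
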