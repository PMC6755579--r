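---
title: "Chaos-embedded swarm docking: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaos-embedded swarm docking: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaosdock)
```

## The docking problem and the search space

Rigid-receptor, flexible-ligand docking asks for the conformation of a small
molecule that minimizes an empirical interaction energy inside a protein
pocket. `chaosdock` encodes a ligand conformation as a vector of dimension
$D = 7 + n_{tors}$: the Cartesian position of the ligand root center (3),
a unit quaternion for the rigid orientation (4), and one dihedral angle per
rotatable bond. Rotatable bonds come from the PDBQT torsion tree
(`ROOT`/`BRANCH` records): each branch rotates its moved atoms about the
parent-to-child bond axis, right-handed, with angles wrapped to
$(-\pi, \pi]$.

## Scoring

Poses are scored with the Vina-family empirical function: for every
heavy-atom pair within an 8 Å center-distance cutoff, a weighted sum of
two attractive Gaussians of the surface distance $d = r - R_i - R_j$,
a quadratic steric repulsion for $d < 0$, a hydrophobic contact ramp
(both atoms carbon/halogen), and a hydrogen-bond ramp (donor--acceptor
pairs):

$$ e(d) = w_1 e^{-(d/0.5)^2} + w_2 e^{-((d-3)/2)^2} + w_3\,d^2\,[d<0]
        + w_4\,h(d) + w_5\,g(d), $$

with $h$ a linear ramp $1 \to 0$ over $d \in [0.5, 1.5]$ and $g$ a linear
ramp $1 \to 0$ over $d \in [-0.7, 0]$. The shipped weights
($-0.035579$, $-0.005156$, $0.840245$, $-0.035069$, $-0.587439$) and the
torsion penalty ($w_{rot} = 0.05846$, applied as the divisor
$1 + w_{rot} n_{tors}$ that converts intermolecular energy to the reported
affinity) are the published defaults of that function; all are overridable
through `scoring_params()`. Donor status is a per-atom property: a heavy
atom is a donor when a polar hydrogen (`HD`) lies within covalent range in
the reference geometry. There is no electrostatic term: although PDBQT
carries partial charges, this scoring family does not use them.

The search objective is $(E_{inter} + E_{intra})$ under the same divisor,
so search and reporting share one convention; intramolecular pairs are
heavy atoms in different rigid bodies at least four covalent bonds apart.
Two evaluation paths exist (cell-list neighbor search and a direct double
loop) and are required by the tests to agree to $10^{-10}$.

The analytic gradient is assembled from per-atom derivatives: the
translation block is the net force, the orientation block is the torque
about the root center pulled back through the normalized quaternion (so the
objective is well defined and differentiable for any non-zero quaternion
the optimizer may produce), and each torsion derivative is the projection
of the moved atoms' torque onto the rotated bond axis. Tests require
agreement with central finite differences to $10^{-4}$.

## The chaotic maps

Five chaotic maps serve as deterministic random-number sources: logistic
($\alpha = 4$), Singer ($\mu = 1.07$), sinusoidal ($\alpha = 2.3$), tent
(the optimization form with breakpoint 0.7), and Zaslavskii
($v = 400$, $r = 3$, $a = 12$; the auxiliary state is advanced first,
$y' = \cos(2\pi x) + e^{-r}y$, then $x' = (x + v + a y') \bmod 1$ — the
standard formulation of that two-state map). A stream
(`chaotic_stream()`) draws its start from the map's admissible chaotic set
(logistic: $(0,1)\setminus\{0.25, 0.5, 0.75\}$; sinusoidal:
$[0.45, 0.92]$; Singer/tent: $(0,1)$; Zaslavskii: $x_0 \in [0,1)$,
$y_0 = 0$) using a self-contained Park–Miller generator, so streams never
touch R's global RNG. In floating point, chaotic iterations can collapse
onto fixed points (logistic at $0.75$, tent reaching exactly $0$); a step
landing outside $(0,1)$ or within $10^{-12}$ of such a point transparently
re-seeds the stream from the admissible set. This degeneracy handling is a
numerical necessity, not part of the maps' mathematics, and it is exercised
directly by the tests.

Two dynamical facts matter downstream and are verified empirically by the
test suite and the acceptance script: sinusoidal iterates started in
$[0.45, 0.92]$ stay above $0.4$ (so that map never produces small
multipliers), and the Zaslavskii auxiliary state is bounded,
$|y| \le 1/(1 - e^{-r}) \approx 1.052$. One caveat we document rather than
hide: the Singer attractor at $\mu = 1.07$ spans roughly $[0.019, 0.996]$
— its iterates remain in $(0,1)$ but never visit the lowest two percent of
the unit interval, so unlike the logistic map it is not fully ergodic on
$(0,1)$.

## The optimizer

The global search is particle swarm optimization. In the chaos-embedded
velocity rule, the inertia weight and the acceleration randomness are
replaced by two chaotic variables drawn once per particle per generation
from independent streams:

$$ V' = w_{cm} V + c_1 r_{cm}(\mathrm{pbest} - X)
      + c_2 (1 - r_{cm})(\mathrm{gbest} - X), $$

with the cognitive and social random weights deliberately coupled
($r_{cm}$ and $1 - r_{cm}$). The stock baseline uses constant inertia
$w = 0.36$ and independent uniform $r_1, r_2$. Default swarm settings are
$N = 8$ particles for docking ($16$ for screening), $c_1 = c_2 = 0.99$,
two-stage local-search ratio $R = 0.1$, and stall limit $C_r = 18$:
the search ends when the swarm best has not improved by more than
$10^{-4}$ kcal/mol for 18 consecutive generations (or at the generation
cap, default 300).

Each generation, every freshly moved particle receives a *two-stage* BFGS
local search: a short probe of $\max(1, R \cdot \text{full})$ steps decides
whether the particle is promising; only if the probe beats the particle's
personal best does the refinement spend the remaining budget. The full
budget defaults to $10 D + 30$ steps, scaling with problem size the way
the AutoDock-family heuristics do. Giving stage 2 the *remaining* rather
than the full budget keeps the two-stage procedure within the one-stage
step budget, which we consider the defining property of the scheme (it
focuses effort, it does not add effort). The BFGS itself uses backtracking
Armijo line search, returns the best point *evaluated* (so a local search
can never report a value above its start), and aborts on non-finite
objectives.

Two geometric refinements apply only inside the docking engine: attraction
differences toward pbest/gbest take the shortest angular path for torsion
coordinates, and flip the sign of the target quaternion when the two
orientations sit on opposite sheets of the double cover ($q$ and $-q$ are
the same rotation). The exported velocity-update operations remain the
literal textbook rules; the engine supplies the geometry through a
difference hook. Velocities are clamped to half the box length
(positions), 1 (quaternion components) and $\pi$ (torsions).

Reproducibility: one master seed fans out to per-run, per-particle and
per-stream sub-seeds through a fixed integer hash (`split_seed()`), so the
same inputs and seed give byte-identical poses, and changing the particle
count or map does not perturb unrelated draws.

## Docking protocol

`dock()` runs $n$ independent searches (default 10, each from its own
sub-seed), ranks the resulting poses by affinity, de-duplicates them at
1 Å heavy-atom RMSD (keeping the lower affinity; at most 9 modes), and
reports the best-scoring pose first — the best-of-repeats protocol used in
redocking evaluation. A predicted pose within 2 Å heavy-atom RMSD of the
crystal pose (no superposition, receptor frame, no symmetry correction)
counts as a success. Boxes come either from pocket atoms (center = their
geometric center, lengths = per-axis extents, degenerate axes padded to
1 Å) or from the bound ligand (cubic, default edge 22.5 Å).

## Virtual screening and metrics

`screen()` docks each library ligand once (a single run, 16 particles) and
returns the table ranked by affinity; parse or docking failures are
recorded, not fatal. AUC-ROC is the rank-sum probability that a random
active outranks a random decoy, ties counted one half — identical to the
trapezoidal area under the full-resolution ROC curve. The enrichment
factor at $x\%$ uses a top bin of $\lfloor x\% \cdot n \rfloor$ ligands
(minimum 1; the definition does not fix the rounding, and floor with a
floor of one is the conservative choice), with boundary ties broken by
ligand id for determinism.

## What the synthetic fixtures emulate — and what they do not

`make_toy_complex()` plants a known pose: a branched C/N/O ligand (a rigid
four-substituent root, one substituent out of plane so mirror poses lose
their hydrogen bonds, plus a chain of rotatable units) sits inside a
receptor shell molded onto its envelope. Polar ligand atoms face matched
donors/acceptors at hydrogen-bonding surface overlap ($d \approx -0.55$ Å);
carbon shell atoms are ray-marched onto the contact optimum
($d \in [0.05, 0.25]$ Å). Generation verifies the funnel property — the
planted pose must score below the 5th percentile of 1000 random in-box
poses — and everything is byte-deterministic in the seed.

These fixtures exercise every term of the scoring function and give the
optimizer a realistic funnel-plus-clutter landscape, but they are not
chemistry: no real bond-length/angle force field, no ring systems, no
solvent, no crystallographic noise. Passing the recovery tests shows the
search machinery finds planted global minima in small landscapes; it does
not certify accuracy on real protein-ligand complexes. One boundary we
measured and respect: beyond roughly four rotatable bonds the molded-shell
construction no longer guarantees that the planted pose is the *global*
optimum — long chains can fold into alternative arrangements that score
better — so the recovery experiment uses complexes with 0-4 torsions,
where the planted-funnel property is sound. The redocking panel used by
the tests is 20 complexes (torsion counts cycling 0-4, 30-atom pockets),
best of 10 runs each, which one CPU completes in a few minutes.

`make_screening_set()` builds actives as jittered copies of a
pocket-complementary template and decoys as the same molecules with their
polar sites displaced by a `separation` parameter — property-matched
(identical atom counts and torsion trees) but polarity-mismatched, a toy
analogue of decoy construction in screening benchmarks. At
`separation = 0` the two classes are statistically identical (AUC ≈ 0.5 by
construction); at 3 Å the hydrogen-bond complementarity is gone and the
end-to-end screen separates the classes (AUC > 0.9 in the acceptance
test).

## Numerical choices and known limitations

* Termination: improvement threshold $10^{-4}$ kcal/mol; BFGS gradient
  tolerance $10^{-6}$; quaternions renormalized on every projection;
  a zero quaternion maps to the identity.
* The pair interaction is truncated sharply at the 8 Å center distance;
  all terms are $< 10^{-4}$ kcal/mol there, and the continuity test bounds
  the effect.
* RMSD is index-matched and not symmetry-corrected; for ligands with
  topological symmetry this can overstate the error.
* The tent map's optimization form has no free parameter; its breakpoint
  value 0.7 is part of the map definition.
* Intramolecular scoring uses distance-inferred bonds (covalent-range
  thresholds), adequate for prepared PDBQT geometries but not a perception
  algorithm.
* Flexible receptors, grid-map precomputation, Monte Carlo mutation moves
  and symmetry-aware RMSD are out of scope.
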