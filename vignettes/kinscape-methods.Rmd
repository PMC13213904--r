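---
title: "kinscape: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinscape: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinscape)
```

kinscape analyses the conformational landscape of a single protein domain
from a coordinate ensemble: it featurizes frames geometrically, finds slow
collective modes, builds a validated metastable-state kinetic model,
decomposes transition pathways, characterizes each state structurally, and
scores transient (cryptic) cavities.  This vignette explains the models
behind each stage, the parameters that matter, and the choices made where
the design was genuinely open.  Everything here is descriptive: empirical
numbers appear only where the package's own tests or the acceptance script
compute them.

## Featurization

Frames are stored in nm with one shared atom table (`trajectory()`); PDB
input is converted from Angstrom on read.  Three descriptor families are
provided:

* **Pair distances** (`pair_distance_features()`), between side-chain
  centres of mass or C-alpha atoms.  The side-chain COM is the
  mass-weighted mean of heavy atoms beyond C-beta inclusive; glycine falls
  back to its C-alpha.  This convention matches common featurizers and
  makes exhaustive enumeration of an n-residue chain yield exactly
  `n(n-1)/2` columns (3003 for 78 residues; 903 for the 43-member
  hydrophobic subset).  The hydrophobic class defaults to
  `{ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO}` and is configurable, since
  no universal definition exists.
* **Backbone torsions** (`backbone_torsion_features()`), phi/psi encoded
  as (cos, sin) pairs — the only encoding consistent with a
  `4(n-1)`-column count (308 for 78 residues) and the natural choice for
  linear methods on periodic angles.
* **Angular descriptors** (`angular_descriptors()`): C-alpha quadruple
  dihedrals for inter-helix reorientation, and aromatic ring-plane angles
  computed from least-squares planes over all ring heavy atoms, folded to
  [0, 90] degrees so the value is invariant to ring flips and atom
  ordering.

## Slow modes, feature ranking, and scoring

`estimate_tica()` implements reversible TICA: with mean-free data and lag
tau, it symmetrizes the instantaneous and time-lagged covariances,
`C(0) <- (C00 + Ctt)/2`, `C(tau) <- (C(tau) + C(tau)')/2`, and solves the
generalized eigenproblem `C(tau) v = lambda C(0) v`.  Implied timescales
follow as `-tau/log(lambda)`.  A small diagonal ridge (default 1e-8)
guards against numerically singular covariances; the default is kept this
small so that IC projections stay uncorrelated at lag 0 to tighter than
1e-6 on training data, and it can be raised (e.g. 1e-6) for heavily
redundant feature sets, where it leaves the leading eigenvalues unchanged
to the same order.  Component signs are fixed by making each component's
largest-magnitude loading positive, so correlation signs are reproducible.

`feature_ic_correlation()` ranks raw features by absolute Pearson
correlation against the leading IC projections, with candidate and strong
flags at 0.45 and 0.70.  Ranking uses absolute correlation (the signed
alternative would depend on the arbitrary IC orientation); the IC set
defaults to the first six and can be restricted (e.g. to components 1, 2,
5, 6 when intermediate components are dominated by terminal fluctuations).

`prune_redundancy_locality()` enforces the registry-hygiene rules on
residue-pair candidates: pairs touching the termini (margin default 3
residues) or near the diagonal (`|i-j| <= 4` by default) are removed
first, then a deterministic greedy pass in order of decreasing absolute
correlation keeps at most one pair per 3x3 index neighbourhood, breaking
ties towards the lexicographically smaller pair.  The margin and window
defaults are package choices — only the neighbourhood size is canonical —
and both are exposed as arguments.  The filter is idempotent and is tested
against an exhaustive brute-force oracle.

`vamp2_score()` computes the VAMP-2 score as 1 plus the sum of the
`dim - 1` largest squared singular values of
`C00^{-1/2} C0t Ctt^{-1/2}` on mean-free data, i.e. `dim` modes counting
the constant.  Scores are nested in `dim` and bounded below by 1.

## Markov state model estimation

The discretization (`cluster_kmeans()`) is seeded k-means; for large
inputs the centres are fitted on a deterministic subsample (default cap
1e5 frames) and all frames are assigned to the nearest centre, so results
are reproducible and memory stays flat.  Transition counting
(`count_transitions()`) defaults to sliding windows, and the active set is
the largest strongly connected component of the count graph.

`estimate_reversible()` maximizes the likelihood over reversible
transition matrices by the standard fixed-point iteration on symmetric
edge weights, converging to `max |Delta T| < 1e-10`; for symmetric counts
the row-normalized counts are the exact fixed point.  Detailed balance of
the result holds to the same order.  `sample_posterior()` draws from the
Bayesian posterior over reversible transition matrices with a
Metropolis-Hastings sampler in the same parameterization (log-normal
multiplicative proposals; a scale-invariant edge prior makes the
acceptance ratio the likelihood ratio).  Every sample is itself a valid
reversible model, and chains are seeded.

Coarse-graining (`coarse_grain()`) fits a discrete-output hidden Markov
model over the microstates at the model lag.  It is initialized from the
spectral metastability structure of the microstate matrix using a
PCCA-style inner-simplex vertex search — plain k-means on eigenvector rows
was evaluated first and discarded, because it splits large metastable
blocks and lumps sparsely populated ones when populations differ by an
order of magnitude, exactly the regime of interest here.
Expectation-maximization (500 iterations maximum, relative log-likelihood
tolerance 1e-6) refines the transition and emission matrices, with the
initial state distribution tied to the stationary law of the current
transition matrix.  Membership weights are the posterior
`P(hidden state | microstate)`.  Asking for as many macrostates as active
microstates returns the exact identity coarse-graining.  Uncertainty is
propagated by lumping each microstate-level posterior sample through the
fixed membership weights (`coarse_grain_posterior()`).

The number of macrostates is chosen by `select_n_macrostates()` from the
spectral gap: `n` metastable states are resolved by `n - 1` slow implied
timescales followed by a drop, so the scan picks the count maximising the
consecutive-timescale ratio inside the candidate range (default 4 to 8).

Validation uses the Chapman-Kolmogorov test (`ck_test()`): predicted
residence probabilities `(T^k)_mm` against re-estimates from the data at
lag `k tau` with strided counting (so counts are not double-used), Wilson
95% intervals on the estimated side, and the posterior spread on the
predicted side when an ensemble is supplied.  A cell passes when the
intervals overlap.  Note that lumping a chain whose metastable sets
exchange uniformly is exactly Markov (lumpable), so a too-coarse model
only fails the test when the merged sets have heterogeneous kinetics; the
test suite constructs such a counterexample deliberately.

Kinetic summaries (`summarize_kinetics()`) report lifetimes via the
geometric-dwell formula `tau / (1 - T_mm)`, relaxation timescales from the
macrostate eigenvalues, and stationary populations, each summarised over
the posterior by mean, SD, and a 1-3 component Gaussian mixture selected
by BIC (via mclust).  Mean first-passage times solve the linear
first-passage system; set-to-set values are stationary-weighted over the
source set.

## Transition path theory

`committors_and_flux()` solves the forward committor on intermediate
states, obtains the backward committor from the time-reversed chain
(`1 - q+` for reversible models), and assembles gross fluxes
`f_ij = pi_i q-_i T_ij q+_j`, net fluxes `max(f_ij - f_ji, 0)`, and the
total flux out of the source set.  `decompose_pathways()` uses the
standard iterative bottleneck (widest-path) decomposition with
deterministic tie-breaking (shorter path, then lexicographic order),
subtracting each path's bottleneck flux until the requested coverage
(default 90% of total flux) is reached.  Shares are reported as
percentages of the total flux — not of the decomposed part — matching the
convention in which listed pathways sum to roughly the coverage target.

## State characterization

Frames are assigned to macrostates by argmax membership of their
microstate (ties to the lower index); frames outside the active set are
reported as unassigned and excluded from summaries.  Backbone hydrogen
bonds use explicit geometric windows — H...O distance 0.15-0.40 nm and
N-H...O angle 100-180 degrees, measured at the hydrogen (the at-H
convention is adopted and documented because the angle vertex is otherwise
ambiguous).  Amide hydrogens are constructed at 0.101 nm along the
direction opposing the bisector of the N-CA and N-C(previous) bonds when
the ensemble lacks them.  The donor's own residue and its predecessor are
excluded as acceptors (the preceding carbonyl is covalently adjacent).

Secondary structure uses a reduced DSSP-like rule built on those same
windows, keeping the module self-consistent with the hydrogen-bond
analysis: helix for residues covered by two consecutive `i+4 -> i` bonds;
strand for residues in ladders of at least two adjacent inter-strand bonds
with sequence separation of at least 5 (which excludes helical i+3/i+4
contacts); coil otherwise, with helix taking priority.  This
deliberately simplified rule reproduces ideal helix and antiparallel
hairpin fixtures exactly but does not implement DSSP's full bridge
taxonomy (bulges, pi/3-10 helices), so borderline real-protein
assignments will differ from DSSP.

## Cavity detection

Alpha-spheres are circumspheres of Delaunay tetrahedra of heavy-atom
centres: tangent to four atoms, containing none.  The triangulation is an
incremental Bowyer-Watson implementation; input points receive a
deterministic sub-angstrom jitter to break exact degeneracies (ideal
fixtures are exactly symmetric) and the reported spheres are recomputed
from the original coordinates.  Radii are filtered to [0.30, 0.60] nm by
default — the conventional pocket-probe window — and a sphere is apolar
when at least 3 of its 4 contact atoms are carbon or sulfur.

Sphere centres are accumulated on a 0.2 nm grid (8 cubic-angstrom cubes)
as mean counts per frame, voxels at or above the isovalue (default 2) are
retained, and retained voxels are clustered into cavities by
26-connectivity.  Frames must be superposed to a common reference first;
the grid is meaningless otherwise.  Cavity volume is the union volume of
the member spheres by sub-voxel sampling at 0.25 Angstrom — chosen, after
measuring the alignment bias of coarser samplings, so that single- and
two-sphere unions agree with closed forms to about 1%.  The mean local
hydrophobic density sums, over apolar spheres, the number of overlapping
apolar neighbours (centre distance below the sum of radii) and divides by
the apolar-sphere count; a cavity with no apolar sphere scores 0.  Across
states, cavities are matched by voxel-set Jaccard overlap (threshold 0.5)
against the reference state, and unmatched cavities are listed rather than
dropped.

## The synthetic ground-truth generator

Because no deposited trajectories exist for the system that motivated this
pipeline, every stage is validated against a generator with known answers.

`build_ground_truth_chain()` constructs a reversible six-state per-step
transition matrix from symmetric exchange weights on a hub topology: a
dominant closed pair (stationary weights 0.62 and 0.24), a hub
intermediate (0.05), and three open states (0.04, 0.03, 0.02) reachable
through the hub, with open-state interconversion routed through one of
them.  The minor-state split is a package choice inside the 2-5% band that
the dominant-pair values leave available.  Detailed balance gives the
stationary law exactly (to 1e-12 by construction).  The uniform exchange
weight (1e-4 per step) was fixed at design time so that state lifetimes
(about 70 to 3000 steps) are long against the default 10-step model lag
and the slowest relaxation (about 1300 steps) is well sampled by runs of
1e6-1e7 steps.  The per-step time unit defaults to 0.1 ns; the
`mfpt_calibration` option rescales it so the analytic hub-to-open MFPT
equals a requested physical time, which is how microsecond-regime
kinetics are emulated at desk scale.

Emissions (`emission_model()`) are per-state Gaussians in an
18-dimensional descriptor space: state `m` is displaced by `separation`
standard deviations (default 6) along dimension `m`.  The default makes
states nearly perfectly resolvable, which is the right regime for testing
estimator correctness; shrinking the separation degrades microstate
purity monotonically, and the suite uses that to check the resolvability
trend.  No emission parameter is read off any published figure.

What passing recovery tests do show: discretization, reversible
estimation, HMM coarse-graining, the macrostate-count scan, MFPTs and TPT
reproduce the known chain within sampling uncertainty.  What they do not
show: robustness to overlapping emissions, non-Markov memory from fast
orthogonal degrees of freedom, force-field or solvent realism — real
trajectories have all three.

Structure fixtures (`build_structure_fixtures()`) cover the
geometry-facing stages: an ideal alpha-helix (phi = -57, psi = -47); an
antiparallel hairpin built from two strands at (-165, 164) — chosen
because that conformation has an almost exactly untwisted two-residue
repeat, so the partner strand is a rigid two-fold image and the
amide-carbonyl ladder closes at canonical hydrogen-bond geometry — a
fully extended chain; a 78-residue chain with full backbone, side-chain
placeholders, planar aromatic rings, and exactly 43 hydrophobic-class
residues (the residue range 77-154 is adopted for the fixture only, being
the count consistent with the printed featurizer sizes); and a hollow
two-layer carbon shell whose 3.3 Angstrom lateral spacing and 6 Angstrom
layer gap keep wall-tetrahedron circumspheres inside the default probe
window at any shell radius, making detected cavity volume grow
monotonically with the radius.

## Problem sizes and reproducibility

All stochastic steps take explicit seeds, and fixed seeds give
bit-identical generator output.  The test suite runs the full recovery at
10 trajectories of 60,000 steps (6e5 steps total), where the
correlation-inflated 95% interval on the dominant population is a few
percentage points; the acceptance script runs 50 trajectories of 200,000
steps (1e7 total), tightening that interval to about 1.5 points.  These
sizes are the package's choice of a desk-scale experiment that still
separates all six states cleanly.

## Known limitations

* The pipeline is single-chain: multi-chain assemblies, solvent and ions
  are out of scope, as are SASA-based analyses.
* The reduced secondary-structure rule is self-consistent with the
  hydrogen-bond windows but is not full DSSP.
* The HMM refinement does not constrain the macrostate transition matrix
  to reversibility; reversibility is enforced at the microstate level and
  holds for the lumped posterior samples only approximately.
* Binary trajectory formats are supported only through a caller-supplied
  reader function; the built-in reader handles multi-model PDB.
* MFPTs from a lag-tau model carry an O(tau) discretization offset;
  with the default settings the model lag is three orders of magnitude
  below the slow passage times, so the offset is negligible.
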