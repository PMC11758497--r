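---
title: "Methods: water-channel geometry, proton pathways, and conformational kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-channel geometry, proton pathways, and conformational kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porekin)
```

porekin analyzes molecular trajectories of membrane proteins that form
transient aqueous channels — the motivating system is a light-harvesting
antenna complex whose photoprotective switch is coupled to a pH-gated
water/proton channel reaching a chlorophyll carboxylate group.  The
package covers the full analysis stack such a study needs: channel
geometry, water structure and orientation, directed water transport,
proton-pathway energetics, protonation-coupled excitonic couplings, and
conformational kinetics by Markov state models.  Because production
trajectories of such systems run to tens of microseconds and are rarely
deposited, every stage is validated against seeded synthetic generators
with analytically known ground truth.

Conventions: coordinates in nm, times in ps, energies in units of kT,
charges in elementary charges, couplings in cm^-1.  The membrane normal
is the +z axis and boxes are orthorhombic (triclinic input is rejected).
Atom indices are 1-based.

## Pore-radius profiling

The channel is profiled by sphere maximization: at each slice z the
radius reported is the largest sphere centered in the slice plane that
touches no atomic van der Waals surface,

$$ r(z) = \max_{c \in \mathbb{R}^2} \; \min_i \big( \lVert x_i - (c, z)
\rVert - r^{\mathrm{vdw}}_i \big), $$

with full 3-D minimum-image distances (not slice-restricted), the
sphere-based definition of the classic channel-profiling algorithm.  The
in-plane maximization uses simulated annealing: 2000 uphill-only Gaussian
proposals per slice, step s.d. halved every 500 trials from 0.05 nm,
moves longer than `max_center_step` (0.1 nm) rejected, each slice seeded
from the previous optimum.  Defaults (`dz` = 0.025 nm, radius cap
`r_max` = 1.5 nm) resolve features of ~0.1 nm, the scale of interest for
a water channel whose accessible radius is a few tenths of a nm.  The
annealer is validated against an exhaustive 0.01 nm in-plane grid search
at every slice; the two agree within 0.02 nm on the cylinder fixture, and
the annealer can never return less than the radius at its starting
center.  Because the vdW radius set used by channel-profiling tools is
rarely reported, the bundled Bondi-style element table is a documented
default, overridable per topology.  Slices whose best radius is negative
are flagged blocked; what radius distinguishes "open" from "closed" is
left to the user, since the boundary is a continuous profile.

Profiles are computed per frame; state-resolved curves (e.g. per
conformational macrostate) come from `average_profiles()` over the frames
assigned to each state, with blocked slices excluded and per-slice counts
reported.

## Water structure

**RDF.** `compute_rdf()` uses the standard normalization
$g(r) = \langle n(r) \rangle / (4\pi r^2 \Delta r \rho)$ with
$\rho = N_{\mathrm{targets}}/V$, averaged over reference atoms and
frames.  The uncertainty band is the spread across consecutive frame
windows; window length is expressed in frames so synthetic and real
trajectories share one code path.  `first_minimum()` smooths g(r) with a
3-bin moving average and returns the first local minimum after the first
local maximum — the construction used to place the 0.35 nm coordination
cutoff at the first minimum of the hydronium-water RDF.

**Dipole order parameter.** The water dipole direction is the normalized
sum of the two O→H vectors (the H-bisector of the rigid 3-site geometry);
partial charges are deliberately not used so the observable is
model-independent.  cos φ is its z component; waters are binned by oxygen
z (default bin width 0.1 nm), per-frame bin means are then averaged over
frames.  Whether to average all waters in a slab or only channel waters
is ambiguous in practice, so a cylindrical `radial_cutoff` is optional
and off by default.  The profile is exactly odd under global z
reflection.

**Coordination number.** The smooth neighbor count uses the rational
switching function $s(r) = (1-(r/r_0)^n)/(1-(r/r_0)^m)$, continuous at
the cutoff where it equals n/m.  Exponents default to (6, 12) — the
common rational form; the cutoff (default 0.35 nm) is the first RDF
minimum.  The hard count (r < r0) is always reported alongside; the two
agree when all distances are far from the cutoff.

## Water transport

**Directed current.** The current through a cylindrical region is the
OLS slope of the cumulative per-step z displacements (minimum-image,
so wrapping is unwound) of waters inside the region, after discarding a
leading transient (default 20%, mirroring the discard of the first fifth
of a force-pulse window).  A water contributes a step when it is inside
the region at the step's start.  The residuals of a cumulative
displacement series are an integrated random walk, so the iid OLS
standard error would be badly anticonservative; the reported
`slope_std_error` uses Var(slope) = (6/5) s²/(N dt²) with s estimated
from the per-step increments, exact for a Brownian path.  Displacement
summing is the primary estimator because short forced windows yield few
complete permeations; full traversal events are counted as the secondary,
event-based estimator.

**Density and immobile waters.** The time-averaged density grid deposits
a normalized 3-D Gaussian per selected atom per frame (width sigma,
default 0.08 nm — about half of a 1.6 Å map resolution — truncated at
4 sigma, grid integral = atoms per frame within 1e-3).  This real-space
Gaussian average carries the information needed to locate persistent,
"immobile" water sites; computing crystallographic structure factors
with tabulated form factors is out of scope.  Occupancy of a voxel is
the fraction of frames with an atom in its 27-voxel neighborhood.
Immobile sites are local density maxima with occupancy at or above a
threshold (default 0.7 — a required, documented choice, since no
standard value exists), greedily pruned to a minimum separation, highest
peak first, ties to the lower voxel index.  Site detection is invariant
to a uniform background density.

## Proton-pathway energetics

The 2-D free-energy surface is the Boltzmann inversion of a (optionally
weighted) sample histogram, $F = -\ln(P/P_{\max})$, so the global
minimum is exactly 0 kT.  Bins with no samples are masked and treated as
impassable, not as F = 0 — unexplored means unknown, not favorable.

The minimum-energy path is Dijkstra's algorithm on the 8-connected graph
of visited bins.  The edge weight is the mean of the two bin energies
times the Euclidean center distance (kT nm): a node-cost-only rule would
make diagonal moves artificially cheap, while this rule is
metric-consistent and is shared verbatim by the test oracles (an
independent graph library and, on small grids, literal enumeration of
simple paths).  Ties are broken by lexicographic bin index so paths are
deterministic.  Adding a constant c to all bin energies changes a path's
cost by exactly c times its geometric length.

Tracer-protein contacts are per-residue frequencies of any
heavy-atom-tracer minimum-image distance below a cutoff (default
0.45 nm, the common heavy-atom contact convention).  The random-force
sampling that generates tracer trajectories in production studies is an
MD-engine task; here the Boltzmann walker on a prescribed surface stands
in as the sample source with known ground truth.

## TrESP excitonic couplings

The coupling between two pigments is the Coulomb sum over atomic
transition charges,
$V = f K \sum_{i \in A}\sum_{j \in B} q_i q_j / r_{ij}$, with
K = e²/(4πε₀) = 11614.1 cm⁻¹ nm e⁻² and no dielectric screening by
default (f = 1, overridable; none is standardly agreed).  Charges map
onto atoms by name, so the mapping is independent of atom storage order;
pair distances below 0.05 nm abort the calculation, since overlapping
charge clouds invalidate the point-charge approximation.

Protonation-state switching: a pigment with both protonated and
deprotonated charge sets uses the deprotonated set until the first frame
at which the minimum probe-target distance (e.g. hydronium to
carboxylate) drops below the threshold (default 0.5 nm), and the
protonated set from then on.  The switch latches because it models a
single protonation event along a steered trajectory; a frame-wise mode
is available behind `latch = FALSE`.  In the far field the coupling
follows the ideal dipole-dipole form κ μ_A μ_B / R³; the toy two-charge
pair converges to it as (d/R)², which the tests exploit quantitatively.

## Conformational kinetics

The kinetics stack is: backbone torsions → (sin, cos) features → tICA →
k-means microstates → reversible MSM → implied timescales, CK
validation, PCCA+ macrostates, and a stationary-reweighted free-energy
surface over the two leading independent components.

Torsions use the standard atan2 dihedral construction, emitted as
(sin, cos) pairs so features are continuous across the angular wrap.
Which torsions production studies use is rarely fully specified; the
default is backbone φ/ψ of user-given residue ranges, with an explicit
quad list overriding.

tICA solves $\bar C_\tau v = \lambda (C_0 + \varepsilon I) v$ with the
symmetrized lagged covariance; covariances never accumulate across
trajectory boundaries, and a small ridge (1e-8) guards rank deficiency.
Components are sorted by eigenvalue; the cumulative VAMP-2 score is
reported as $1 + \sum \lambda_i^2$, including the constant singular
function, so scores are comparable across runs.  The number of
components kept (3 by default in the pipeline stage) follows the VAMP-2
plateau.

The MSM uses sliding-window counts (never across trajectory boundaries)
symmetrized as (C + Cᵀ)/2 and row-normalized.  This closed-form
reversible estimator is exactly stationary and detailed-balanced by
construction (residual < 1e-12 on any input), which we prefer over
iterative reversible likelihood maximization or Bayesian sampling at
validation scale; uncertainty comes from a bootstrap over trajectories
(or over 10 contiguous blocks when only one trajectory is available).
Implied timescales are $-\tau \Delta t / \ln \lambda_i$; states outside
the largest connected count component are dropped with a message.

PCCA+ builds macrostates by the inner-simplex construction on the top
right eigenvectors: the most extreme microstate seeds the first vertex,
each further vertex is the microstate farthest from the span of the
chosen ones, memberships follow from the linear transform onto the
simplex, clipped at zero and renormalized; crisp labels are the argmax
with ties to the lowest index.  The Chapman-Kolmogorov test compares
$[\mathrm{coarse}(T(\tau))^k]_{AA}$ with
$[\mathrm{coarse}(T(k\tau))]_{AA}$ under π-weighted crisp aggregation;
it passes when every prediction falls inside the bootstrap 95% interval
of the estimate.  Defaults k = 100 microstates and 4 macrostates mirror
the scale used for the FCP system; both are parameters.

Frame weights for the reweighted surface are π(cluster)/count(cluster),
so the histogram reflects the MSM stationary distribution rather than
raw sampling.

## Synthetic generators: what they emulate, and what they do not

`make_membrane_channel_system()` builds an immobile cylinder of lining
pseudo-atoms through a slab (geometric radius minus lining radius gives
a known accessible radius), filled with rigid 3-site waters
(|O-H| = 0.09572 nm, 104.52°) whose dipole orientations follow a
prescribed mean-cos φ profile m(z).  cos φ is drawn uniformly on
[m - Δ, m + Δ] with Δ = (1 - |m|)/√(1 + κ): the mean is exactly m(z) for
every κ, κ = 0 with m = 0 reproduces the isotropic distribution, and
κ → ∞ is deterministic — giving analytic control of the order-parameter
observable.  Waters are resampled independently each frame.

`make_markov_feature_trajectories()` emits torsion angles from a hidden
Markov chain with known relaxation timescales $-\Delta t / \ln
\lambda_i$; `make_drift_diffusion_waters()` produces independent 1-D
walks with expected summed displacement rate n·v;
`make_boltzmann_walker()` is Metropolis sampling of a prescribed energy
grid; `make_toy_chromophore_pair()` gives two-point-charge dipoles with
exact closed-form couplings.  All generators are bit-reproducible under
a fixed seed.

These generators deliberately omit much of real data: no protein
dynamics coupled to water structure, no hydrogen-bond network
correlations between waters, no position-orientation coupling, Markovian
hidden dynamics by construction, and uncorrelated frames.  Passing tests
therefore demonstrate that the estimators recover known ground truth
under their own assumptions — they do not certify behavior on correlated
μs-scale MD, where lag-time and feature choices must be re-validated
with the implied-timescale and CK machinery provided here.

## Validation problem sizes

The package's validation suite uses: an 81-slice cylinder profile
checked against the 0.01 nm grid oracle; an ideal-gas RDF with 1000
targets over 100 frames; orientation-field recovery from 50 waters over
200 frames (10^4 water-frames per bin); drift-diffusion flux with
(v, D, n, steps) = (0.01 nm/ps, 0.01 nm²/ps, 50, 1000), averaged over 5
generator seeds since a single run of this size carries ~8% standard
error; a 10^6-step walker on a 12x8 double-well surface (recovery within
0.3 kT); 100 random ≤12x12 grids against the independent shortest-path
oracle; and a 2x10^5-frame 4-state hidden-Markov fixture for the full
kinetics pipeline (slowest timescale within 20%, macrostate agreement
≥ 90%, CK pass at k ∈ {2, 3, 5} and fail for a period-3 counterexample).

## Known limitations

Orthorhombic boxes only; straight z-aligned channel axes (no spline
axes); no hydrogen-bond topology or tetrahedral order parameters; no
transition-state rates from the FES; no Bayesian MSM posteriors or
hidden Markov MSMs; transition charges are user input, never computed;
XTC trajectories must be converted to DCD or multi-model PDB first.
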