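# porekin

Trajectory analysis for pH-gated water and proton channels in membrane
light-harvesting proteins.

Diatom antenna complexes (fucoxanthin-chlorophyll proteins, FCP) switch
to a photoprotective state when the thylakoid lumen acidifies.  One
proposed mechanism runs through a transient water channel that lets
protons reach a buried chlorophyll-c2 carboxylate: protonation changes
the pigment's transition charges and thereby its excitonic coupling to
the carotenoid quencher.  Studying such a mechanism in molecular
dynamics trajectories requires a broad analysis stack, which this
package provides as tested, reusable R functions:

- **Channel geometry** — sphere-maximization pore-radius profiles along
  the membrane normal, `r(z) = max_c min_i (|x_i - (c,z)| - r_vdw,i)`,
  with a Monte-Carlo annealer validated against an exhaustive grid
  search (`compute_radius_profile`).
- **Water structure** — radial distribution functions with windowed
  uncertainty, first-minimum location, the dipole orientational order
  parameter cos φ(z), Plumed-style rational-switching coordination
  numbers `s(r) = (1-(r/r0)^n)/(1-(r/r0)^m)`, and pair-distance
  distributions.
- **Transport** — directed water currents from cumulative displacement
  fits with a random-walk-aware standard error, permeation-event
  counting, Gaussian-smeared density grids, and immobile-water site
  detection by high-occupancy density peaks.
- **Proton pathways** — 2-D free-energy surfaces `F = -ln(P/Pmax)` (kT),
  Dijkstra minimum-energy paths on the visited-bin graph, and
  tracer-residue contact maps.
- **Excitonics** — TrESP couplings `V = f K Σ q_i q_j / r_ij` (cm^-1)
  with one-way protonation-state charge switching at a distance
  threshold.
- **Kinetics** — torsion featurization, tICA, k-means microstates,
  reversible Markov state models with implied timescales,
  Chapman-Kolmogorov validation, PCCA+ macrostates, and MSM-reweighted
  free-energy surfaces.
- **Synthetic data** — seeded generators with analytic ground truth for
  every stage (membrane channel systems with a controllable water
  orientation field, hidden-Markov torsions, drift-diffusion walkers,
  Boltzmann walkers, toy chromophore pairs).

See `vignettes/channel-analysis.Rmd` for the methods account.

## Worked example

Build a synthetic membrane channel (geometric pore radius 0.55 nm,
lining atom radius 0.15 nm, so the accessible radius is 0.40 nm by
construction) with a water orientation field m(z) = tanh(z), then
profile the pore and the water dipole order:

```r
library(porekin)

tr <- make_membrane_channel_system(
  pore_radius = 0.55, lining_atom_radius = 0.15,
  n_waters_channel = 40,
  orientation_profile = function(z) tanh(z),
  orientation_concentration = 8, seed = 42)

lin  <- select_atoms(tr$topology, resname = "LIN")
spec <- channel_spec(seed_point = c(0, 0, 0), z_min = -1, z_max = 1,
                     dz = 0.25)
compute_radius_profile(tr$frames[[1]], tr$topology, lin, spec,
                       n_trials = 1000, seed = 1)[, c("z", "radius")]
#>       z radius
#> 1 -1.00    0.4
#> 2 -0.75    0.4
#> ...
#> 9  1.00    0.4

sys <- make_membrane_channel_system(
  n_waters_channel = 50, n_frames = 100,
  orientation_profile = function(z) tanh(z),
  orientation_concentration = 8, seed = 42)
compute_order_profile(sys, seq(-1.5, 1.5, 0.5))
#>   z_center mean_cos_phi count
#> 1    -1.25       -0.850   909
#> 2    -0.75       -0.622   788
#> 3    -0.25       -0.241   827
#> 4     0.25        0.242   789
#> 5     0.75        0.624   799
#> 6     1.25        0.848   888
```

The profiler recovers the constructed 0.40 nm accessible radius at every
slice, and the binned order parameter tracks tanh(z) (bin means average
the field over each 0.5 nm bin, hence -0.85 rather than tanh(-1.25) =
-0.85 exactly here; agreement is within sampling error of the imposed
field).

A command-line entry point wrapping the same functions is installed at
`inst/cli/porekin.R` (`Rscript porekin.R <stage> <config.yaml>
[key=value ...]`); each stage writes TSV/JSON outputs plus a
resolved-config copy, and exits 0/1/2 for success / runtime error /
config error.

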