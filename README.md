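# kinscape

Markov state modelling and cryptic-pocket analysis of protein
conformational ensembles in R.

Proteins that look rigid in a crystal structure often visit rare, open
conformations in which transient ("cryptic") cavities appear — prime
targets for drug design when the dominant state offers no pocket.
Resolving those excursions from simulation data requires a kinetic model,
not just snapshots: which metastable states exist, how probable they are,
how slowly they interconvert, and along which pathways.  kinscape
implements that workflow end to end for a single protein chain:

* **Featurization** — side-chain centre-of-mass and Cα–Cα distances,
  backbone φ/ψ torsions as (cos, sin) pairs, inter-helix Cα dihedrals and
  aromatic ring-plane angles (`pair_distance_features()`,
  `backbone_torsion_features()`, `angular_descriptors()`).
* **Slow-mode feature selection** — reversible TICA
  (`C(τ) v = λ C(0) v` on mean-free, symmetrized covariances;
  `t_i = −τ/ln λ_i`), correlation-based ranking with candidate/strong
  thresholds 0.45/0.70, redundancy/locality pruning, and VAMP-2 scoring
  (`estimate_tica()`, `feature_ic_correlation()`,
  `prune_redundancy_locality()`, `vamp2_score()`).
* **Markov state models** — seeded k-means microstates, sliding-window
  counts, reversible maximum-likelihood estimation with detailed balance
  to 1e−10, Bayesian posterior sampling, implied timescales
  (`cluster_kmeans()`, `count_transitions()`, `estimate_reversible()`,
  `sample_posterior()`, `implied_timescales()`).
* **Metastable coarse-graining** — PCCA-initialized discrete-emission
  hidden Markov model at the model lag, spectral-gap selection of the
  macrostate count, Chapman–Kolmogorov validation, lifetimes
  `τ/(1 − T̃_mm)`, relaxation timescales and MFPTs with GMM posterior
  summaries (`coarse_grain()`, `select_n_macrostates()`, `ck_test()`,
  `summarize_kinetics()`, `mfpt()`).
* **Transition path theory** — committors, net reactive fluxes
  `f⁺_ij = max(π_i q⁻_i T_ij q⁺_j − …, 0)`, and iterative bottleneck
  pathway decomposition with flux shares
  (`committors_and_flux()`, `decompose_pathways()`).
* **State characterization** — hydrogen bonds under explicit windows
  (H···O 0.15–0.40 nm, N–H···O 100–180°), a reduced DSSP-like H/E/C rule,
  per-state RMSF, radius of gyration and descriptor distributions
  (`detect_hbonds()`, `assign_secondary_structure()`,
  `per_state_summary()`).
* **Cryptic cavities** — α-spheres (circumspheres of Delaunay tetrahedra
  tangent to four atoms), per-frame frequency grids at isovalue 2 per
  8 Å³ cube, cavity volumes and mean local hydrophobic density
  (`compute_alpha_spheres()`, `pocket_frequency_grid()`,
  `cavity_metrics()`, `per_state_cavity_report()`).
* **Ground truth** — a reversible six-state hidden chain with hub
  topology and known stationary law (62%, 24%, and four minor states),
  Gaussian emissions, and ideal structure fixtures, so every stage is
  testable against known answers (`build_ground_truth_chain()`,
  `sample_feature_trajectories()`, `build_structure_fixtures()`).

## Worked example

Recover the generator's landscape from simulated feature trajectories,
then score a cavity on a hollow-shell fixture:

```r
library(kinscape)

chain <- build_ground_truth_chain()
sim <- sample_feature_trajectories(chain, emission_model(),
                                   n_traj = 4, n_steps = 50000, seed = 42)

fit <- estimate_pipeline(sim$features, n_micro = 100, lag_frames = 10,
                         seed = 1, n_samples = 25)
fit$macro_selection$n_macro
#> [1] 6
round(100 * sort(fit$macro_model$pimacro, decreasing = TRUE), 1)
#> [1] 60.9 25.7  5.4  3.1  2.5  2.5

mt <- match_macrostates(fit, sim$labels)
A <- which(mt$map == which(chain$states == "S6"))  # dominant closed state
B <- which(mt$map == which(chain$states == "S1"))  # terminal open state
net <- committors_and_flux(fit$macro_model, A, B)
decompose_pathways(net)$paths
#>                    path         flux share_pct cumulative_pct
#> 1           1 -> 3 -> 4 4.045973e-04     50.38          50.38
#> 2 1 -> 2 -> 3 -> 5 -> 4 2.117601e-04     26.37          76.74
#> 3 1 -> 3 -> 6 -> 5 -> 4 8.600409e-05     10.71          87.45
#> 4                1 -> 4 4.033903e-05      5.02          92.48

shell <- build_structure_fixtures("cavity_shell", R = 0.8)
spheres <- compute_alpha_spheres(shell)
map <- pocket_frequency_grid(list(spheres), spacing = 0.2, isovalue = 2)
met <- cavity_metrics(map, which.max(lengths(map$cavities)))
c(volume_A3 = round(met$volume_A3), density = round(met$density, 1))
#> volume_A3   density 
#>   10937.0      81.1
```

The macrostate scan over 4–8 candidates selects six states; the two
dominant recovered populations bracket the generator's 62% and 24% within
the sampling uncertainty of a 2×10⁵-step run, and the leading transition
pathways out of the closed state pass through the hub intermediate
(state 3 here), as built into the generator topology.  The shell cavity
is reported with its voxel-union volume in Å³ and the mean number of
overlapping apolar α-sphere neighbours per apolar sphere.

See `vignettes/kinscape-methods.Rmd` for the models, parameter defaults,
and design decisions.

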