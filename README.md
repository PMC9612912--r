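# ligpath

Ligand binding **pathway** analysis for molecular dynamics trajectories.

Unbiased MD of a clamshell ligand-binding domain (LBD) — the kind found in
ionotropic glutamate receptors — shows agonists associating with the protein
surface hundreds of times per microsecond, while only a handful of those
encounters end with the ligand docked in the binding cleft. `ligpath` is a
toolkit for everything between raw coordinates and that mechanistic story:

- **Binding chains** — one association episode per chain, opened when any
  polar ligand heavy atom comes within 6 Å of any polar protein heavy atom
  and closed when the ligand diffuses beyond 10 Å of the protein (the 6/10 Å
  gap is a hysteresis band). Chains are filtered by a **docking** criterion:
  the conserved arginine's NH1/NH2 engaging the ligand carboxylate OT1/OT2
  within 4 Å, in either the crystallographic or the flipped orientation.
  Docked chains are split into a *binding* pathway (association → first
  docked frame) and a time-reversed *unbinding* pathway (last docked frame →
  dissociation).
- **Pathway similarity analysis (PSA)** — pairwise weighted-average Hausdorff
  distances

  δ<sub>H</sub><sup>wavg</sup>(A,B) = ½ [ δ<sub>H</sub><sup>sum</sup>(A|B)/|A| + δ<sub>H</sub><sup>sum</sup>(B|A)/|B| ],  δ<sub>H</sub><sup>sum</sup>(A|B) = Σ<sub>a∈A</sub> min<sub>b∈B</sub> d(a,b)

  clustered hierarchically with Ward (or complete) linkage, plus per-cluster
  ligand occupancy densities written as OpenDX grids.
- **Residue contact profiling** — fractional occurrence relative to the most
  contacted residue (label at ≥ 0.2, display at ≥ 0.1), overlap-coefficient
  set comparisons OC(A,B) = |A∩B| / min(|A|,|B|) per cluster versus the
  global pair mean, agonist-vs-agonist fold-change contrasts, and a
  conditional success-probability census of associations.
- **Kinetics** — the association rate constant from bulk-time accounting,
  k<sub>on</sub> = N<sub>b</sub> / Σ<sub>i</sub> t<sub>i</sub> [L<sub>i</sub>] s<sub>i</sub>,
  with residence-time thresholds giving an upper bound (all events) and
  lower bounds (long-lived events only).
- **Order parameters & free energy** — LBD closure distances (ξ1, ξ2) and
  their mean ξ12, the glycan–D2 minimum-distance order parameter, histogram
  PMFs (0.2 Å bins, 5-block errors), 2D WHAM unbiasing of harmonic umbrella
  windows (10-block errors), and ≤ 1 kcal/mol low-energy conformer
  extraction.
- **Synthetic generators** — a toy two-lobed receptor, scripted
  ligand-diffusion trajectories with exact ground-truth event logs, and
  exact Boltzmann samples from analytic 2D potentials under umbrella biases,
  so the whole chain is testable offline.

Units throughout: Å, ns, kcal/mol, K; atom ids 0-based; residue numbering
preserved verbatim.

## Worked example

```r
library(ligpath)

rec <- make_toy_receptor(seed = 3, n_residues = 30, n_copies = 3)
sim <- simulate_binding(rec, n_frames = 300, dt = 0.2, seed = 101,
                        mode = "guided", rate_per_ns = 0.05)
print(sim$trajectory)
#> <lp_trajectory> 300 frames x 152 atoms, 0-59.8 ns

chains <- unlist(lapply(0:2, function(cp) detect_chains(sim$trajectory, cp)),
                 recursive = FALSE)
print(chains[[1]])
#> <lp_chain> copy 0 frames 33-59, 16 docked, terminated=TRUE

paths <- unlist(lapply(chains, split_chain, traj = sim$trajectory),
                recursive = FALSE)
binding <- Filter(function(p) p$direction == "binding", paths)
length(binding)
#> [1] 8

cl <- cluster_paths(path_distance_matrix(binding), k = 2)
print(cl)
#> <lp_clusters> 8 paths, 2 clusters (ward linkage)

sets <- lapply(binding, function(p) as.integer(names(p$contact_residues)))
oc <- cluster_oc_profile(sets, cl$labels)
round(oc$global_mean, 3)
#> [1] 0.69

res <- kon_from_trajectory(sim$trajectory, count = "docked",
                           residence_thresholds = c(0, 2))
res$kon
#>   threshold_ns n_b         kon
#> 1            0   8 26013412220
#> 2            2   8 26013412220
```

The 11 detected chains match the generator's ground-truth log exactly; 8 of
them dock and yield binding pathways, which Ward clustering separates into
the two planted approach routes (sizes 6 and 2). Both clusters' mean overlap
coefficient (1.0 — every pathway in a cluster touches the same rail
residues) exceeds the global pair mean of 0.69, the signature of *guided*
rather than random diffusion. The k<sub>on</sub> is enormous compared to a
real receptor because the toy generator plants an association attempt every
~20 ns to densify events; it is the planted value the estimator recovers,
not a physical prediction.

## Command line

```sh
Rscript -e 'ligpath::ligpath_cli()' simulate --out run1 --seed 42 --frames 400
Rscript -e 'ligpath::ligpath_cli()' detect   --out run1
Rscript -e 'ligpath::ligpath_cli()' cluster  --out run1 --k 2
Rscript -e 'ligpath::ligpath_cli()' contacts --out run1
Rscript -e 'ligpath::ligpath_cli()' kinetics --out run1
Rscript -e 'ligpath::ligpath_cli()' report   --out run1
```

Each stage reads the previous stages' CSV/JSON artifacts from `--out` and is
byte-for-byte deterministic given the same config and seed; every output
embeds the package version and a config hash.

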