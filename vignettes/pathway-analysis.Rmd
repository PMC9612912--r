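---
title: "Binding pathways, contact specificity and free energy: the methods behind ligpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding pathways, contact specificity and free energy: the methods behind ligpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligpath)
```

## The problem

A clamshell ligand-binding domain (LBD) captures its agonist in a cleft
between two lobes (D1 above, D2 below) and closes around it. In unbiased MD
at millimolar agonist concentrations the ligand collides with the protein
surface constantly; almost all of these encounters are unproductive. The
scientific questions `ligpath` addresses are: *which* surface encounters
become productive binding events, *where* on the LBD surface the ligand
travels on its way in (and out), whether those routes rely on specific
guiding residues or on unguided diffusion, *how fast* association is, and
how the LBD's conformational free-energy landscape (and its glycans) shapes
all of the above.

## Binding chains and docking

The central bookkeeping object is the **binding chain**, one continuous
association episode per ligand copy:

* a chain **opens** at the first frame where any polar ligand heavy atom is
  within `assoc_cutoff` = 6 Å of any polar protein heavy atom;
* it **survives** while the ligand's minimum heavy-atom distance to the
  protein is ≤ `dissoc_cutoff` = 10 Å;
* it **closes** at the last frame before that distance exceeds 10 Å.

The asymmetric atom sets are deliberate: association is a polar–polar event
(hydrogen-bond-competent contact), while dissociation asks whether the
ligand has genuinely left the protein's neighborhood, so all heavy atoms
count. "Polar" means element N, O or S; the criterion itself does not
specify whether sulfur counts, so the element set is configurable
(`polar_elements`), with N/O/S as the shipped default. The 6→10 Å gap is a
hysteresis band: a ligand rattling between 6 and 10 Å neither opens a new
chain nor closes the current one, which keeps one physical visit from being
counted as many. `chain_intervals()` exposes this state machine on raw
distance series so it can be tested against scalar oracles.

**Docking** is the event that distinguishes productive chains: the
conserved arginine's guanidinium nitrogens NH1/NH2 must each be within 4 Å
of one of the ligand carboxylate oxygens OT1/OT2, in either pairing
(NH1–OT1 ∧ NH2–OT2, or the flipped NH1–OT2 ∧ NH2–OT1). Docking is
evaluated at every chain frame, not just at the ends.

A docked chain is split into at most two **pathways**: the binding pathway
runs from chain start through the *first* docked frame; the unbinding
pathway runs from the *last* docked frame to the chain end and is stored
time-reversed so all pathways share one directionality. Intermediate
undock/redock excursions stay inside the chain and spawn no extra pathways,
keeping pathway counts commensurate with chain counts; because the spatial
metric below is order-free, this choice does not affect clustering.
Chains that never dock contribute no pathways but still count as (failed)
associations in the census and kinetics.

`classify_mechanism()` tags a pathway "free" when fewer than
`min_distinct_residues` (default 3) distinct surface residues — excluding
the docking arginine — were contacted before the first docked frame. The
exact guided-vs-free rule is inherited from prior practice and is not
uniquely determined here; the threshold is a configurable stand-in and is
echoed in the result attributes so downstream tables carry it.

## Pathway similarity analysis

Two pathways are geometrically similar when each point of one lies near
some point of the other, regardless of traversal speed or frame count. The
**weighted-average Hausdorff distance** encodes exactly that:

$$\delta_H^{wavg}(A,B) = \tfrac12\Big[\tfrac{1}{|A|}\,\delta_H^{sum}(A|B)
 + \tfrac{1}{|B|}\,\delta_H^{sum}(B|A)\Big],\qquad
\delta_H^{sum}(A|B)=\sum_{a\in A}\min_{b\in B} d(a,b)$$

Normalizing each one-sided sum by its own frame count means a pathway
sampled twice as densely is not twice as important — duplicating every
point of A leaves the value unchanged (a tested invariant). The measure is
symmetric, non-negative and zero exactly for equal point sets, but the
triangle inequality is **not** guaranteed: it is a similarity score, not a
metric, and the package documents rather than hides this.

Clustering is agglomerative on the precomputed distance matrix. Ward
linkage (`ward.D2` on the unsquared distances, matching the common SciPy
convention) is the default even though Ward formally presumes Euclidean
geometry; complete linkage is offered as the assumption-free alternative
and recovers the same planted partitions in the test fixtures. The cluster
count is user-chosen (default cut k = 4): automatic selection is a
non-goal, and the dendrogram plus per-cluster occupancy densities (OpenDX
grids) are always available, mirroring how practitioners actually choose
cuts — by eye, against the spatial density. Distances are computed in the
laboratory frame; this is appropriate when the protein is
center-of-mass-restrained during simulation (as the synthetic generator
guarantees). For unrestrained input, align frames to a reference before
detection.

## Contact specificity

Per cluster, residues are ranked by the number of *pathways* that contact
them (a residue counts once per pathway); frame-level counts are carried
alongside because display conventions differ, and the chosen basis is
recorded. **Fractional occurrence** is the count relative to the most
contacted residue in scope, so the top residue is exactly 1; residues at
≥ 0.2 are labeled and at ≥ 0.1 displayed — the two tiers are exposed as
thresholds, not hard-coded.

Whether a cluster reflects *specific* guidance or random surface contact is
quantified with the **overlap coefficient** OC(A,B) = |A∩B|/min(|A|,|B|)
over the contact sets of every pathway pair: OC is 1 whenever one set nests
inside the other, which is why it (and not Jaccard) is the right tool when
pathway lengths differ wildly. A cluster whose mean pairwise OC falls below
the global mean over all pathway pairs carries the signature of random
contacts. The global mean is a partition-independent statistic (tested).
`compare_agonists()` contrasts two fractional-occurrence profiles and flags
residues exceeding a fold-ratio (default 10×), with a pseudo-count for
residues absent from one profile so the ratio is defined and the absence is
annotated.

## Kinetics

The association rate constant is estimated as

$$k_{on} = \frac{N_b}{\sum_i t_i\,[L_i]\,s_i}$$

with \(t_i\) the time each ligand copy spends in **bulk** (neither
associated nor docked), \([L_i]\) the free-agonist concentration of that
segment (computed from the box volume and the mean number of free copies,
or supplied as a nominal constant), and \(s_i\) the number of identical
sites. The estimator is additive under trajectory concatenation and
monotone non-increasing in the residence threshold — both asserted as
properties. Because short-lived events dominate raw counts, \(k_{on}\) is
reported as a band: threshold 0 (all events) gives the upper bound and a
user threshold (100 ns is the conventional reference) the lower bound.
"Association event" defaults to docked chains, with `count = "all"`
available since the appropriate \(N_b\) depends on the threshold question
being asked. No correction is applied for under-sampling of the closed
bound state; the sensitivity band is the honest substitute.

## Order parameters and free energy

LBD closure is measured by ξ1 and ξ2, mass-weighted center-of-mass
distances between backbone (N, CA, C) residue groups spanning the clamshell
mouth; `lobe_presets` ships the published residue ranges for the two
receptor subunits, overridable for any system. Whether the reference
implementation mass-weighted its centers is unstated; mass weighting is the
default here and the geometric option exists (`mass_weighted = FALSE`) —
for backbone triads the difference is negligible. ξ12 = (ξ1+ξ2)/2 is the 1D
closure projection; the glycan–D2 order parameter is the minimum heavy-atom
distance between a near-pocket glycan and the D2-lobe Cα atoms.

**Histogram PMFs** invert bin probabilities, F = −kT ln p, on 0.2 Å bins
(default) and are min-zeroed; unsampled bins are +∞, never 0. Uncertainty
comes from block averaging with 5 blocks (equilibrium data) or 10 blocks
(umbrella data): the PMF is recomputed per contiguous block and the per-bin
standard deviation taken across blocks, omitting blocks that do not sample
a bin. Block PMFs are gauge-aligned to the full PMF by their *mean* offset
over shared bins: a free energy is defined only up to an additive constant,
and anchoring each block at its own noisy minimum would fold that
gauge noise into every error bar. Temperatures are explicit: 310 K is the
default for equilibrium-trajectory PMFs, 300 K for umbrella data.

**2D WHAM** solves the standard self-consistent equations for harmonic
per-axis biases ½k(ξ1−ξ1°)² + ½k(ξ2−ξ2°)², iterating the per-window free
energy constants to |Δf| < 10⁻⁷ kcal/mol (default; max 10⁵ iterations,
failure to converge is an error carrying the residual). The converged PMF
is invariant to a constant shift of the initial window constants — the
gauge-invariance acceptance property. Bin width defaults to 0.25 Å per
axis, a decision (the reference spacing of windows is 1 Å but the analysis
bin size is unstated). Windows whose histograms share no sampled bins
cannot be placed on a common energy scale; the connectivity check warns and
reports the disconnected grouping rather than silently stitching them.
`low_energy_conformers()` maps frames back onto PMF bins and returns those
within 1 kcal/mol (default) of the minimum — the bound-ensemble input for
contact profiling. `conditional_pmf()` stratifies an order parameter by a
closure predicate (e.g. ξ12 < c); the closed/open threshold is user
supplied because no universal value exists. An empty stratum yields a
warning and a NULL slot rather than an error, so the degenerate
"condition always true" case reduces to the unconditioned PMF.

## The synthetic world

The generators are first-class, tested code, and they state a world rather
than tune one:

* `make_toy_receptor()` builds a two-lobed point-cloud receptor (default 40
  pseudo-residues, lobe radius 7 Å, lobes ±7 Å about the box center) with a
  protruding docking arginine whose NH1/NH2 tips are the only polar atoms
  in the docking corridor, an optional 8-heavy-atom glycan, and a
  140 × 110 × 110 Å box matching the simulated system size whose
  concentration arithmetic the kinetics module mirrors. It is synthetic by
  construction — a geometric stand-in, not a model of any real structure.
* `simulate_binding()` moves serine-like rigid 6-atom ligand copies
  (N, CA, CB, OG, OT1, OT2 — so the polar and carboxylate criteria are
  exercised literally) by reflected random walks with exponential
  (memoryless) waiting times at per-site rate k<sub>on</sub>[L], scripted
  approaches, a docking probability (default 0.7), and Poisson-length
  docked dwells. Guided mode follows one of two surface "rails" hugging the
  D1 or D2 lobe (~2 Å above the surface), which both accumulates guiding
  contacts and defines the planted cluster identity; free mode dives
  straight down the docking corridor. The ground-truth log is derived from
  the emitted coordinates by a self-contained criterion scan *inside the
  generator* — deliberately sharing no code with `detect_chains()` — so
  the log is exact by construction while remaining an independent check.
  The default `kon = 1e8 M^-1 s^-1` reflects a realistic diffusion-limited
  agonist; tests shorten waits via `rate_per_ns` to densify events in
  desk-scale trajectories (the implied k<sub>on</sub> is logged either
  way).
* `sample_umbrella()` draws *exact* Boltzmann samples of
  exp(−(U+bias)/kT) by rejection from a uniform proposal over a
  window-local box (8 bias standard deviations) with an envelope certified
  on a fine grid (×1.05 headroom). Uniform proposals are used instead of
  the bias Gaussian because windows sitting high on the potential — e.g.
  spanning a barrier — would otherwise reject essentially everything; the
  truncation beyond 8σ is ~e⁻³² relative density, the numerical analogue
  of the flat-bottom restraint used in practice to keep umbrella windows
  near their centers.

What a green test therefore establishes: the detection logic, metrics,
estimators and solvers are exact or statistically calibrated on data whose
truth is known. What it does not establish: anything about force fields,
water, real protein flexibility (the toy protein is rigid), rotational
ligand dynamics (the toy ligand translates without rotating), or the
physical value of any rate or barrier in a real receptor.

## Numerical choices and edge cases

* Distances are non-periodic by default (solute assumed whole and
  centered); an orthorhombic minimum-image mode exists behind a flag.
* Empty selections error unless explicitly allowed; empty contact sets are
  excluded from OC with a warning; a zero denominator in k<sub>on</sub> is
  an error while zero surviving events returns 0 with a warning.
* Clustering ties are resolved by `hclust`'s deterministic merge order;
  identical inputs give identical dendrograms, asserted byte-for-byte
  through the CLI.
* DCD I/O is single-precision by format; round-trip tests tolerate 1e-5 Å.
  PDB coordinates carry 3 decimals, tolerance 5.1e-4 Å.
* Config files are a flat `key: value` subset (no nesting) because the
  toolchain targets zero non-base dependencies beyond `jsonlite`.

## Known limitations

* The weighted-average Hausdorff "distance" may violate the triangle
  inequality; dendrogram heights are therefore heuristic (as in the field's
  standard practice).
* Ward linkage on a non-Euclidean dissimilarity is a documented
  approximation; complete linkage is the conservative fallback.
* The guided/free classifier is a residue-count stand-in, not a mechanistic
  committor.
* WHAM assumes uncorrelated samples within windows; no autocorrelation
  correction is applied (block errors absorb slow drift only partially).
* The kinetics module implements no correction for conformational
  under-sampling of the closed state; only the residence-threshold band.
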