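---
title: "quenchscape: models, parameters and design choices"
author: "quenchscape authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and scientific setting

Minor light-harvesting complexes such as CP29 switch between a
light-harvesting and a photoprotective (quenched) state, and the switch is
believed to be conformational: the protein scaffold repositions its
carotenoids (lutein in site L1, violaxanthin in L2) relative to the
chlorophylls, modulating both the long-range Coulomb part and the
short-range overlap part of the couplings that drive quenching, and tuning
the carotenoid S1 energy through the geometry of the conjugated chain.
quenchscape implements the post-simulation side of this analysis: it takes
a conformational ensemble as input (it does not run MD or any
enhanced-sampling method) and turns it into conformational states,
collective variables, per-frame pigment couplings and Marcus
charge-transfer rates. Quantum-chemical quantities — S1 energies, CT-state
energies, reorganization energies, screened couplings — are consumed as
external tables, never computed.

# The ensemble container

`ConformationalEnsemble` stores frames × atoms × 3 coordinates in Ångström
with a single shared topology (chain, residue name/number, atom name,
element) and optional non-negative frame weights. Weights default to
uniform; they exist because enhanced-sampling ensembles are typically
reweighted, and they enter every density-like quantity (weighted PCA mean
and covariance, free-energy surfaces, RMSF). Multi-model PDB is the one
supported interchange format (`readMultimodelPDB`/`writeMultimodelPDB`,
via bio3d); binary trajectory formats are deliberately out of scope —
convert upstream.

# Dihedral PCA

`computeDihedrals` evaluates torsions with the IUPAC right-hand-rule sign
convention; the quadruple (0,1,0),(0,0,0),(1,0,0),(1,0,1) yields +90° and
this convention is pinned by a test. Angles live in (−π, π]; a torsion with
collinear central atoms is undefined and flagged `NA` for that frame
rather than failing the whole ensemble.

The default feature set is backbone φ, ψ plus sidechain χ1 (N–CA–CB–CG)
where those atoms exist. χ1 alone is the default because it is the
sidechain angle definable on nearly every residue type and the leading
sidechain degree of freedom; further χ angles can be added by passing a
custom dihedral spec, but are not enumerated by default.

Each angle θ is embedded as (cos θ, sin θ) before PCA — the standard dPCA
construction. The embedding removes the ±π branch cut (a basin straddling
the cut stays one blob), at the price of doubling the feature count and
placing the data on a torus rather than a plane; for well-concentrated
basins this distortion is negligible. `fitDihedralPCA` is a
weighted-mean-centred eigendecomposition of the weighted covariance
C = Xᶜᵀ diag(w) Xᶜ / Σw. Eigenvalues are therefore *population-style*
weighted variances, and the projection of the fitting data reproduces them
exactly as score-column variances (a tested identity). Component signs are
made reproducible by forcing the largest-magnitude loading of each
component positive (ties by lowest feature index). Three components are
retained by default; the first two usually separate the major basins while
the third distinguishes close-lying states.

Free-energy surfaces use direct Boltzmann inversion of a 2-D weighted
histogram, F = −k_BT ln(w_bin / w_maxbin), so the most occupied bin sits
at F = 0 and empty bins are `Inf` (undefined, not zero). This estimator is
exact on bin counts — a 1 : e occupancy ratio gives ΔF = 1 k_BT identically
— and its sampling error per bin scales as 1/√n; the tests size the
double-well recovery (ΔF = 2 k_BT within 0.2) at 10⁵ samples accordingly.

Per-residue RMSF superposes every frame on the ensemble mean by Kabsch
alignment, refining the mean twice (alignment → new mean → realign); two
passes suffice because the mean moves negligibly after the first. RMSF of
a residue is the weighted RMS deviation of its atoms, so an isotropic
per-coordinate jitter σ yields RMSF = σ√3.

# Conformational states and residue importance

Clustering is agglomerative with Ward linkage on Euclidean distances in
retained-PC space. Ward is the default because free-energy basins in dPCA
projections are compact and variance-based linkage matches that geometry;
the linkage is configurable. The number of states is an explicit user
choice (set it from the free-energy surface; six states is a typical
choice for CP29-like landscapes) — no automatic model selection is done in
the core. Labels are relabeled by descending cluster size, ties by first
occurrence, so cluster 0 is always the dominant state and reruns are
stable.

Residue importance asks which dihedrals determine state identity. For each
feature the (cos, sin) embedding is split by cluster and the correlation
ratio η² = SSB/(SSB+SSW) computed — the between-cluster share of the total
embedded variance. η² was chosen over the raw F statistic because it is
bounded in [0, 1] and finite even when a feature is noise-free within
clusters (F diverges there, and that is exactly the interesting case of a
perfectly discriminating dihedral). It is monotone in F at fixed group
sizes, so rankings agree. A residue scores the maximum over its features;
ties rank by residue number.

Representative frames per state come from greedy farthest-point (max–min)
sampling seeded at the cluster medoid, all ties broken by lowest frame
index. On small instances the greedy selection is max–min optimal
(verified by brute force in the tests); in general it is the standard
2-approximation, which is ample for picking geometry-optimization
candidates.

# Collective variables

The inter-helical torsions P1_l and P1_s are torsions of four node points
A2–A1–B1–B2, each node the centre of geometry of a configured atom group
(typically Cα atoms of a few consecutive residues on helix A or B). The
residue ranges defining the nodes are configuration, not constants: they
depend on the helix assignment of the particular complex. The documented
default — splitting each helix at its midpoint into a lumenal and a
stromal half and using the three terminal Cα atoms of each half — is a
placeholder and is echoed into the output metadata so downstream users see
exactly which atoms defined their CV.

Carotenoid conjugated-chain dihedrals d1..dN are all consecutive 4-atom
torsions along a user-declared ordered atom list, counted from the lumenal
end. The s-cis/s-trans classification uses |angle| < 90° → s-cis with the
boundary assigned to s-trans; the threshold is the symmetric midpoint
between the two conformer wells at 0° and 180°, chosen because no
experimentally privileged cutoff exists and a symmetric rule is exactly
testable.

Box-plot summaries (per-cluster dihedral or energy distributions) use
type-7 (linear interpolation) quartiles, whiskers at the most extreme
point within 1.5 IQR of the box, and an outlier list. For angular data the
`circular` option recentres values about their circular mean before
computing quartiles, applied only when the linear spread exceeds 90°;
narrower distributions cannot straddle the branch cut, and recentring them
would only relabel values.

# Pigment couplings

The Coulomb coupling is the exact double sum V = K Σ qᵢqⱼ/rᵢⱼ over the two
pigments' transition charges — no distance cutoff, because pigment pairs
are small and a cutoff would bias the far tail that the dipole limit test
(log–log slope −3 over 50–500 Å) checks. K converts e²/Å to cm⁻¹ and is
assembled once, in a centralized CODATA 2018 constants table, as
(Hartree in cm⁻¹) × (Bohr radius in Å) = 116 140.973 cm⁻¹·Å/e²; the tests
cross-check it against the independent e²/(4πε₀Å)/(hc) route to 1e-10.
The implementation (one matrix product) is held to 1e-12 relative
agreement with a naive double loop.

The overlap parameter replaces each heavy atom by a rigid sphere of Bondi
van der Waals radius times a single global scale factor s, and sums the
analytic sphere–sphere intersection (lens) volumes across the pair. The
lens formula covers all regimes: 0 beyond contact, the closed-form lens
for partial overlap, and the smaller sphere's full volume at containment.
Hydrogens are excluded by default (negligible density); s defaults to 1
and is exposed because it is the acknowledged free parameter of this
geometric proxy — at s = 1 two van der Waals–contact carbons have just
touching spheres, so values of s around 1.2–1.6 are needed before typical
stacked pigments show nonzero overlap. The lens-volume sum is this
package's concrete definition of the overlap parameter; it captures the
monotone, short-ranged character that makes the parameter a useful proxy
for short-range coupling, and its absolute scale should be calibrated per
application.

# Marcus charge-transfer rates

`marcusRate` implements the classical high-temperature Marcus expression
k = (2π/ħ)|V|²(4πλk_BT)^(−1/2) exp(−(ΔG+λ)²/4λk_BT) with V in cm⁻¹ and
ΔG, λ in eV. The classical form (no quantum modes) was chosen because the
energetics arrive as single numbers from external quantum chemistry, with
no spectral density to support a quantum correction. The implementation is
pinned at three points: the barrierless maximum at ΔG = −λ (exponential
factor exactly 1), the |V|² scaling, and a spot value computed before the
build by an independent constant-assembly script (V = 10 cm⁻¹,
ΔG = +0.2 eV, λ = 0.7 eV, 300 K → 4.2497·10⁵ s⁻¹), matched to 1e-10
relative. `channelActivity` calls a channel active when its rate is at
least a threshold ratio (default 1, boundary inclusive) times the
competing decay rate.

# The synthetic-data generator

The generator exists so the whole pipeline can be tested against planted
truth. It emulates three features of real ensembles:

* **Multi-basin dihedral landscapes.** Frames are assigned to clusters by
  the spec's weight vector; the planted φ dihedrals are drawn from
  per-cluster von Mises distributions (Best–Fisher sampling) and all other
  dihedrals get small Gaussian jitter (default σ = 0.05 rad) around an
  ideal two-helix geometry (α-helical φ/ψ with a short extended loop).
  Coordinates are rebuilt analytically from internal coordinates with
  fixed bond lengths and angles, so the planted circular distributions are
  realized *exactly* in Cartesian space — `concentration = Inf` with zero
  jitter reproduces bitwise-identical frames. Default study conditions for
  recovery tests: 500 frames, 20 residues, three planted residues,
  concentration 30 (circular σ ≈ 10°), basin separations of π (two
  clusters) or 2π/3 (three clusters) — separations ≥ 3 circular standard
  deviations, where hierarchical clustering should and does recover labels
  with ARI ≥ 0.95.
* **Conformer flipping.** An eight-carbon chain whose first torsion is
  drawn near 0° with the planted s-cis probability and near 180° otherwise
  (von Mises concentration 200, σ ≈ 4°, over 20σ from the 90° boundary, so
  classification error is negligible and recovery is limited only by
  binomial sampling — hence the 3-standard-error acceptance bound at
  n = 2000).
* **Pigment pairs at controlled geometry.** Two rigid planar six-atom
  pigments with charge-neutral, dipole-carrying charge patterns at an
  exact separation and relative rotation, giving analytic far-field and
  no-contact limits.

What the generator does **not** emulate: force-field energetics, solvent
and membrane, realistic pigment chemistry, correlated backbone motions, or
reweighting artifacts of enhanced sampling. Passing recovery tests
therefore demonstrates the correctness of the analysis chain — not that
real trajectories contain such clean basins, nor anything about the
free-energy landscape of a real complex.

# Numerical choices and degenerate inputs

* Determinism everywhere: a single integer seed drives each generator; all
  tie-breaks (medoids, farthest-point, importance ranking, cluster
  relabeling, PCA signs) resolve by lowest index; TSV output formats
  numbers with a fixed `%.10g`, making pipeline reruns byte-identical.
* Torsions: collinear triples → per-frame `NA` flag; hard error only for
  atoms missing from the topology. −π maps to +π so the range is (−π, π].
* PCA: eigenvalues clipped at 0 (they can be −1e-17 numerically); zero
  total frame weight is an error.
* Free-energy surfaces: empty bins are `Inf`, never extrapolated; all-zero
  weights error.
* Sphere overlap: the containment and contact branches are handled exactly
  and the lens formula is continuous at both boundaries (tested at 1e-6).
* Coulomb sum: coincident atoms across the two sets (r = 0) are an error,
  not an infinity.

# The pipeline

`runPipeline` chains the stages from one YAML configuration and writes
every intermediate as TSV plus a manifest with MD5 hashes and a
configuration echo. `validateConfig` reports *all* schema and
cross-reference problems at once (missing charge tables, selections that
resolve to no atoms, non-positive cluster counts) before any computation
starts. Stage failures abort with the stage name attached. The default
synthetic study (200 frames, ~500 atoms) completes in a few seconds on one
CPU. Each stage is equally usable as a plain R function, which is the
intended interface for interactive work; `inst/scripts/run_pipeline.R` is
a thin shell wrapper (exit codes: 0 ok, 2 invalid configuration,
1 runtime error).

Problem sizes used in the shipped tests and in `scripts/acceptance.R` —
500-frame recovery ensembles, 2000-frame conformer series, 10⁵-sample
free-energy surfaces, 100×50-atom coupling oracles, a 200-frame end-to-end
study — were chosen so every statistical bound above holds with margin
while the whole suite runs in well under a minute.

# Known limitations

* The overlap parameter is a geometric stand-in with one free scale
  factor; it orders geometries by short-range contact but has no absolute
  electronic meaning.
* Coulomb couplings are unscreened vacuum sums; environment polarization
  and screening are out of scope and typically reduce couplings by a
  factor ~0.7–0.8 in protein.
* P1 node residue ranges and the carotenoid chain atom list are
  system-specific configuration; the defaults are placeholders flagged in
  the output metadata.
* dPCA with sin/cos embedding is linear on the torus; strongly curved or
  multimodal manifolds may need more components than the default three.
* The classical Marcus expression omits nuclear tunnelling; rates in the
  deep inverted region are underestimated.
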