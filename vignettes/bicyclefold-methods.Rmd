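---
title: "Methods: how bicyclefold measures structural diversity in saposin-like effector families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how bicyclefold measures structural diversity in saposin-like effector families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicyclefold)
```

## The problem

Bicycle proteins are a fast-evolving family of aphid salivary effectors,
named for their paired Cys-Tyr-Cys (C-Y-C) motifs. Structure prediction has
made it possible to model thousands of family members at once, and the
recurring observation is a conserved architecture — compact all-helical
saposin-like domains, usually two four-helix bundles per protein — carrying
extremely divergent sequences and surfaces. `bicyclefold` implements the
post-prediction half of such a study as reusable, testable components:
quality-filter the predicted models, encode their backbones, classify their
disulfides and domain topologies, and quantify diversity in sequence space,
structure space, and physicochemical space.

Every stage is exercised against a synthetic-structure generator, so the
whole pipeline is verifiable on a laptop with no external downloads.

## Quality filtering of predicted models

A predicted model is retained when

1. at least a fraction `frac_cut` (default 0.80) of its residues have
   per-residue confidence (pLDDT) of at least `conf_cut` (default 60);
2. it has at least `min_len` residues (default 70) and at least
   `min_helices` helices (default 2); and
3. its sequence identity to every already-kept model is at most
   `dedup_identity` (default 0.99, i.e. models above 99% identity are
   treated as duplicates).

The confidence rule has a second reading — "median pLDDT of at least 60 over
a window covering 80% of the chain" — which `rule = "median_window"`
implements; the fraction reading is the default because it is operationally
unambiguous. Fail reasons are all recorded per model, but stage-wise counts
attribute each rejected model to its first failing stage (confidence, then
length/helix content, then duplicate), so the counts always partition the
input exactly. Deduplication is a greedy, stable scan in input order with
identity defined as 1 − normalized Levenshtein distance; a graph-based
clique treatment would be equally defensible, but greedy scanning is
deterministic and reproduces "remove the later near-duplicate" semantics.

## ABEGO backbone encoding

Backbone dihedrals follow the IUPAC sign convention, reported in degrees in
(−180, 180]. omega of residue *i* is the peptide torsion
CA(i−1)–C(i−1)–N(i)–CA(i). Consecutive residues are treated as bonded only
when the C–N distance is below 1.8 Å (peptide bond ≈ 1.33 Å plus slack);
breaks, termini and backbone-incomplete residues yield undefined dihedrals,
never silent zeros.

Each residue with defined dihedrals maps to one of five states:

* `O` — cis peptide (|omega| < 90°), regardless of phi/psi;
* for phi < 0: `A` (helical) when −75° ≤ psi < 50°, else `B` (extended);
* for phi ≥ 0: `G` when −100° ≤ psi < 100°, else `E`;
* `X` — undefined.

These rectangular Ramachandran bins are the Rosetta-style convention; other
groups draw the `A`/`B` boundary slightly differently, so states at region
edges may differ between implementations. A helix is a maximal run of at
least `min_run = 6` consecutive `A` states — a dihedral-only definition that
needs no hydrogen-bond pass and is exactly reproducible. Each helix carries
a least-squares axis (first principal component of its CA atoms) and its CA
centroid as midpoint.

## Disulfide geometry and strain

Bridges are detected as cysteine SG pairs within `max_ss = 2.4` Å (covalent
S–S ≈ 2.05 Å plus model noise). The five side-chain dihedrals are measured
with the residue pair canonically ordered by (chain, residue number):
chi1 = N–CA–CB–SG, chi2 = CA–CB–SG–SG′, chi3 = CB–SG–SG′–CB′, and the
primed pair mirrored on the second residue.

Classification uses only signs:

* handedness: **LH** when chi3 < 0, **RH** when chi3 > 0 (chi3 = 0 is a
  planar degenerate case and an error);
* base shape from how many of chi2/chi2′ share chi3's sign: both →
  **Spiral**, one → **Hook**, none → **Staple**;
* a sign prefix from chi1/chi1′ (`-`, `+`, or `+/-`), omitted when either
  chi1 is trans (|chi1| > 150°), matching the crystallographic convention of
  reporting a trans chi1 without a prefix.

The dihedral strain energy (kJ/mol) is the torsional-potential estimate

DSE = 8.37 (1 + cos 3chi1) + 8.37 (1 + cos 3chi1′) + 4.18 (1 + cos 3chi2) +
4.18 (1 + cos 3chi2′) + 14.64 (1 + cos 2chi3) + 2.51 (1 + cos 3chi3).

The coefficients are the standard literature values for this potential and
are exposed as an argument for sensitivity analysis. Two useful anchors:
the all-trans bridge scores 29.28 kJ/mol, and the relaxed left-handed spiral
(−60, −60, −90, −60, −60) scores 2.51 kJ/mol, which is also the minimum over
a dense chi grid — consistent with −LH spirals being the most common and
least strained conformation in surveys of disulfide geometry. Note that the
potential is even in every chi, so the Spiral/Hook/Staple classes (which
differ only in sign patterns) do not differ in strain when averaged over
sign-symmetric grids; strain differences between classes in real structures
come from the chi *magnitudes* each class imposes, not from the signs
themselves. When a crystal form contains several copies of a bridge, values
are reported per copy with mean ± sd rather than silently averaged.

## Domain topology: tandem vs helix-swapped

Helices are grouped into bundles by single-linkage clustering of their
midpoints at `link_cutoff = 14` Å. The cutoff sits between the generator's
intra-bundle (< 12 Å) and inter-bundle (> 20 Å) separations; real predicted
models may need tuning, so it is a configuration key. With bundles ordered
by their smallest member, contiguous sequence blocks of the same sizes form
the tandem reference, and the label is:

* `single` — one bundle;
* `tandem` — every bundle is exactly a contiguous block
  ({1,2,3,4}, {5,6,7,8});
* `helix-swapped` — exactly one helix is exchanged between two adjacent
  blocks ({1,2,3,8}, {4,5,6,7}), the alpha4/alpha4′ swap;
* `mixed` — any other multi-bundle pattern (deliberately narrow: broader
  permutations are surfaced, not silently lumped into "swapped");
* `unresolved` — some bundle has fewer than 3 helices.

Authors of structural studies generally make this call by eye; the decision
table here is a formalization chosen to be deterministic and auditable, not
a reimplementation of anyone's code. C-Y-C motifs are counted as
non-overlapping exact `CYC` tripeptides scanned left to right ("CYCYC"
counts once), naming the variants unicycle through hexacycle.

## Sequence and backbone-grammar distances

The family's sequence diversity is measured with the length-normalized
Levenshtein distance D(a,b) = d(a,b) / max(|a|, |b|), where d is the
unit-cost edit distance; the same routine serves amino-acid strings and
ABEGO strings, giving directly comparable distance matrices. The isolation
statistic frac≥T(a) is the fraction of *other* members at distance ≥ T from
a, using the ≥ comparison throughout; it is monotone non-increasing in T.
Hierarchical clustering of either matrix uses average linkage via
`stats::hclust`.

Conservation profiles are per-column Shannon entropies over the 20 amino
acids with gaps excluded from the counts (bits by default; a `base` switch
gives nats). Columns with more than half gaps are flagged low-coverage.
Entropy values map onto a reference structure through the alignment row
whose ungapped sequence must match the structure; mapped values are written
into the B-factor column, the standard trick for coloring a structure by an
arbitrary per-residue quantity.

## SASA and the physicochemical descriptor suite

Solvent-accessible surface area uses the Shrake–Rupley construction with a
deterministic Fibonacci sphere lattice (`n_points = 960` per atom) instead
of random sampling, so results are bit-reproducible. Radii: C 1.70, N 1.55,
O 1.52, S 1.80 Å, probe 1.4 Å; hydrogens are ignored. A single isolated
carbon reproduces 4π(1.70 + 1.4)² to well under 1%, and doubling the point
set moves a bundle's total area by < 0.05%. Residue classes follow the
pH 7 convention with histidine counted positive: hydrophobic
{I,L,V,F,C,M,A,W,Y,P}, positive {K,R,H}, negative {D,E}; nonstandard
residues are excluded from class sums.

The descriptor suite (23 named values per model) combines composition
(n_res, residue-class fractions, net charge (K+R+H)−(D+E), charge per
residue), SASA partitions and their fractions, and shape/surface summaries:

* **surface_hydropathy** — SASA-weighted mean Kyte–Doolittle value. The
  weighting itself suppresses buried residues, so no exposure threshold is
  applied by default; `rsa_cut = 0.2` restores a hard cutoff at 20% relative
  accessibility (Tien-style theoretical maxima), at the cost of the value
  jumping when a residue crosses the threshold.
* **surface_roughness** — the ratio of SASA at the standard 1.4 Å probe to
  SASA at a 3.0 Å smoothing probe. A rugged surface keeps area at the small
  probe that the large probe cannot reach, so larger values mean more
  texture; the index is dimensionless, deterministic, and needs no surface
  mesh. It is one of several defensible texture definitions and is
  implemented as a named, swappable strategy.
* **hydrophobic patches** — connected components (single-linkage, < 6 Å) of
  exposed hydrophobic-residue atoms; reported as patch count, largest patch
  area, and patchiness = largest patch / hydrophobic SASA.
* **amphipathicity** — Eisenberg-scale hydrophobic moments
  mu_H = |Σ H_n (cos n·100°, sin n·100°)| / N over 11-residue windows inside
  helices; reported as the window maximum, the window mean, and the fraction
  of helical residues inside windows with mu_H ≥ 0.25.
* **dipole_asymmetry** — the magnitude of the first moment of ±1 charges at
  CA positions about the CA centroid (e·Å). This is a charge-distribution
  summary, not a Poisson–Boltzmann potential.
* **radius_of_gyration**, **helix_fraction**.

Before embedding, features flagged size-dependent (absolute areas, counts,
n_res, net charge, dipole moment, radius of gyration) are dropped, then
correlated pairs are greedily resolved at |Pearson r| > 0.85, dropping the
member of the worst pair with the larger mean absolute correlation (ties
keep the earlier column). Constant features are dropped with a warning.

A note on numerical stability: the point-set construction makes per-atom
areas exactly reproducible but not exactly rotation-invariant. The total
area is stable to ~0.05% under rigid motion; class partitions (sub-areas)
inherit up to ~0.5%, and near-zero weighted means such as the hydropathy
average are stable to ~0.005 in absolute Kyte–Doolittle units. All
composition-based descriptors are exactly invariant.

## Structure space

TM-score uses d0 = 1.24 (L − 15)^(1/3) − 1.8 (floored at 0.5, and fixed to
0.5 for L ≤ 21), normalized by a target length; identical structures score
1, and a pair whose aligned distances all equal d0 scores exactly 0.5. The
superposition maximizing the score is found by iterated Kabsch fits on the
close-pair subset (d < max(d0, 3 Å)), seeded from the full set and from
contiguous fragments.

`tm_align_lite` is a simplified TM-align: initial alignments come from
gapless threading at all sequence offsets (stride 4) and from a
Needleman–Wunsch alignment of the two ABEGO strings; each is refined by
alternating (a) subset-refined Kabsch superposition of the current aligned
pairs with (b) dynamic-programming re-alignment on the inter-CA distance
score matrix 1/(1 + (d/d0)²) with gap penalty 0.6 and free end gaps, until
the alignment is stable or 20 iterations. The best alignment across all
initializations and iterations is kept and scored under both chain-length
normalizations; the all-vs-all distance matrix uses 1 − mean of the two
normalizations, since neither chain is privileged in a family-wide
comparison. The DP kernel is in C++ (Rcpp); everything is deterministic.

Clustering runs on a k-nearest-neighbor graph of the input metric
(k = 15 by default; edge weight 1 − d/max d) with Leiden community
detection (modularity objective, resolution 1.2) — not on embedded
coordinates, to avoid embedding artifacts. The 2-D embedding (t-SNE with
perplexity 30 for distance matrices, reduced to (n−1)/3 for small n; UMAP
with 30 neighbors and min_dist 0.05 for feature tables) is for
visualization only. Cluster counts are treated as outcomes, never as
constraints. Each cluster is summarized by its medoid, the member
minimizing summed within-cluster distance.

## What the synthetic generator emulates — and what it does not

The generator builds backbones analytically from internal coordinates
(NeRF): ideal helices at (phi, psi, omega) = (−57°, −47°, 180°) with
standard bond geometry, packed on a per-bundle 2×2 lattice with 8 Å spacing
and antiparallel alternation (intra-bundle midpoints < 12 Å apart, bundles
36 Å apart), with loops built as extended strands continuing from the
preceding helix. Sequence order maps to bundles tandem-wise (1–4 / 5–8) or
swap-wise (1,2,3,8 / 4,5,6,7). Disulfides are built forward from the first
cysteine's backbone frame through the five chi targets, and the partner
helix is rigid-body placed onto the bridge-derived frame — giving exact chi
and S–S values with no minimization, at the price that a bridge, not the
lattice, owns the partner helix's position (such helices are exempt from
the lattice separation contract, which the generator re-measures and
enforces for all others; a helix can be re-targeted by at most one bridge).
Sequence families carry planted C-Y-C motifs at fixed positions and a
closed-form mutation rate calibrated so expected pairwise identity matches
the request (the non-motif alphabet excludes C and Y so motif counts stay
exact). Confidence profiles assign a high value to exactly
round-half-up(frac·n) seeded residues. Everything is deterministic given
the seed.

What it does **not** emulate: side chains beyond CB/SG, rotamer libraries,
physically realistic packing or loop closure (loop–helix junctions are
chain breaks by construction), coordinate noise of real predicted models,
and pLDDT's correlation with local geometry. Passing the closed-loop tests
therefore demonstrates that the analyzers recover exactly what was planted
under clean geometry — correctness of the measurement machinery — not that
classification thresholds (bundle cutoff 14 Å, helix run 6, patch 6 Å) are
optimal for noisy real-world models; those remain configuration keys.

## Problem sizes and determinism

The test-suite and the reproduction script use desk-scale problems chosen
to exercise every code path: 50-bridge chi grids, 200-model QC cohorts with
planted failure modes, 10-model all-vs-all TM comparisons (two planted
topology groups), 20-seed topology recovery, 30-sequence identity
calibration, and 600-row alignment entropy checks. All randomness flows
through explicit seeds; rerunning any stage with the same seed reproduces
byte-identical outputs, which the pipeline tests assert file-by-file.

## Known limitations

* The ABEGO bin boundaries are one published convention; encodings of
  residues near region edges are convention-dependent.
* The topology table assumes bundles of 3–5 helices; heavily fragmented
  helices (e.g. from low-confidence models) land in `unresolved`.
* TM-align-lite searches sequential alignments only; circular permutations
  are found only insofar as threading offsets capture them.
* The descriptor suite reconstructs standard definitions where multiple
  variants exist in the literature (roughness, hydropathy weighting,
  patch definitions); its values are internally consistent and
  rigid-motion stable but should not be compared numerically against other
  software without checking the definitions.
* Dedup identity is edit-distance based, not alignment-based; for
  length-divergent pairs this is conservative.
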