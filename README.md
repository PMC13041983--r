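# bicyclefold

Structural diversity analysis for saposin-like effector protein families.

Bicycle proteins are rapidly evolving aphid salivary effectors, named for
their paired Cys-Tyr-Cys (C-Y-C) motifs, that adopt compact all-helical
saposin-like folds — typically two four-helix bundles per protein, arranged
either as tandem sequence blocks or with one helix swapped between bundles.
Structure prediction now yields thousands of models for such families, and
the analytical question shifts from "what is the fold?" to "how diverse is
the family within it?". `bicyclefold` implements that post-prediction
analysis for structural biologists and effector-biology groups:

* **Quality control** — retain models with pLDDT ≥ 60 over ≥ 80% of the
  chain, ≥ 70 residues, more than one helix, and < 99% identity to any
  retained model; stage-wise elimination counts partition the input exactly.
* **Backbone grammar** — phi/psi/omega dihedrals and ABEGO state strings
  (`A` helical, `B` extended, `G`/`E` positive-phi, `O` cis), plus helix
  segmentation with least-squares axes.
* **Disulfide geometry** — S–S bridge detection, the five chi dihedrals,
  conformation classes (LH/RH × Spiral/Hook/Staple with `-`/`+`/`+/-`
  prefixes), and dihedral strain energy
  DSE = 8.37(1+cos 3χ1) + 8.37(1+cos 3χ1′) + 4.18(1+cos 3χ2) +
  4.18(1+cos 3χ2′) + 14.64(1+cos 2χ3) + 2.51(1+cos 3χ3) kJ/mol.
* **Domain topology** — four-helix-bundle grouping and the
  tandem ({1,2,3,4},{5,6,7,8}) vs helix-swapped ({1,2,3,8},{4,5,6,7})
  decision table; C-Y-C motif counting (unicycle, bicycle, tricycle, ...).
* **Sequence & structure spaces** — length-normalized Levenshtein distances
  D(a,b) = d(a,b)/max(|a|,|b|) over amino-acid and ABEGO strings, isolation
  fractions frac≥T(a), hierarchical clustering; all-vs-all TM-scores via a
  simplified TM-align (threading + ABEGO-seeded dynamic programming refined
  by Kabsch superposition), Leiden clustering on the kNN graph of the
  metric, t-SNE/UMAP embeddings, cluster medoids.
* **Physicochemical descriptors** — Shrake–Rupley SASA on a deterministic
  Fibonacci point set with hydrophobic/positive/negative partitions,
  Eisenberg hydrophobic moments and amphipathic helix content,
  Kyte–Doolittle surface hydropathy, surface texture, hydrophobic patches,
  charge summaries; correlation-based pruning (|r| > 0.85) to a
  size-independent feature set.
* **Conservation mapping** — per-column Shannon entropy of an MSA written
  onto a reference structure's B-factors.
* **Synthetic data** — seeded generators for ideal helices, bundles with
  programmable tandem/swapped topology, disulfides with exact chi targets,
  sequence families with controlled identity and motif counts, and
  confidence profiles, so the full pipeline is testable offline.

## Worked example

Generate a helix-swapped two-domain model with one planted disulfide, then
analyze it:

```r
library(bicyclefold)

spec <- bundle_spec(8, 14, 4, "swapped")
bridge <- disulfide_spec(5, 131, chi = c(-60, -60, -90, -60, -60))
res <- build_bundle_model(spec, disulfides = list(bridge), seed = 42,
                          id = "demo")
model <- res$model
model
#> <structure_model> demo: 1 chain(s), 140 residues, 702 atoms

topology_report(model, res$sequence$sequence)
#>   model_id n_helices n_domains topology_label n_cyc_motifs cycle_class
#> 1     demo         8         2  helix-swapped            0     0-cycle
#>           bundles
#> 1 1,2,3,8;4,5,6,7

analyze_disulfides(model)$bonds[, c("resno_a", "resno_b", "ss_distance",
                                    "chi1", "chi3", "geometry_class",
                                    "dse")]
#>   resno_a resno_b ss_distance chi1 chi3 geometry_class  dse
#> 1       5     131        2.05  -60  -90      -LHSpiral 2.51
```

The topology stage found eight helices in two four-helix bundles with
helices 1,2,3,8 packing together — the helix-swapped arrangement — and the
planted bridge is recovered at 2.05 Å with the chi signature of a relaxed
left-handed spiral, the least-strained disulfide class (2.51 kJ/mol under
the strain potential; an all-trans bridge scores 29.28).

Surface descriptors for the same model:

```r
round(surface_descriptors(model)[, c("f_sasa_hydrophobic", "net_charge",
                                     "helix_fraction",
                                     "max_hydrophobic_moment")], 3)
#>   f_sasa_hydrophobic net_charge helix_fraction max_hydrophobic_moment
#> 1              0.447          7          0.686                  0.365
```

For a whole cohort, `run_pipeline(pipeline_config(structures_dir, output_dir))`
chains QC → ABEGO → distance matrices → disulfides → topology → features →
TM structure space → entropy, writing CSV/TSV outputs, a run log and a JSON
manifest; `inst/scripts/bicyclefold-pipeline.R` wraps it for the shell.

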