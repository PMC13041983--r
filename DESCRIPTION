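Package: bicyclefold
Title: Structural Diversity Analysis of Saposin-Like Effector Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-prediction structural analysis of rapidly evolving,
    all-helical effector protein families such as the aphid bicycle proteins.
    Quality-filters predicted models by per-residue confidence (pLDDT), length
    and helical content; encodes backbone geometry as ABEGO state strings;
    detects and classifies disulfide bridges by their five chi dihedrals
    (handedness, spiral/hook/staple, sign prefix) with dihedral strain
    energies; classifies saposin-like domain topology (tandem versus
    helix-swapped four-helix bundles) and counts C-Y-C motifs; computes
    normalized Levenshtein distance spaces over amino-acid and ABEGO strings
    with isolation fractions and hierarchical clustering; derives a
    physicochemical descriptor suite from Shrake-Rupley solvent-accessible
    surface areas; performs all-vs-all TM-score comparison with a simplified
    alignment search, graph-based Leiden clustering, t-SNE/UMAP embedding and
    medoid extraction; and maps per-column Shannon entropy of an alignment
    onto structures. A fully seeded synthetic-structure generator (ideal
    helices, four-helix bundles with programmable topology and disulfide
    geometry, sequence families with controlled identity, simulated confidence
    profiles) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    Rtsne,
    uwot,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
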