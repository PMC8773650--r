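Package: sctraj
Title: Stabilization Center Dynamics in Multi-Chain Protein Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects protein stabilization centers (residue pairs that are
    distant in sequence or on different chains, approach within the sum of
    their van der Waals radii plus a 1 Angstrom margin, and are reinforced by
    dense contacts among their sequence neighbours) in multi-model PDB
    structures and trajectories. Tracks stabilization-center occupancy across
    frames, applies extracellular and occurrence filters, classifies pairs by
    assembly topology (trans-interface, inter-subunit, inter-loop, intra-loop)
    for double-hexamer gap-junction channel models, detects disulfide bonds,
    computes backbone phi/psi/omega dihedrals and a permutation-based
    association statistic between proline psi states and stabilization-center
    presence, and scores per-column consensus agreement on multiple sequence
    alignments. Includes a synthetic toy-assembly generator with exact
    contact-level ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
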