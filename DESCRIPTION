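Package: trajcontact
Title: Residue Contact, Interaction and Fluctuation Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative molecular-interaction analysis of protein
    conformational ensembles supplied as multi-model PDB files:
    residue-residue heavy-atom contact-population maps and their difference
    between two systems, geometric hydrogen-bond and aromatic pi-pi
    interaction detection (including T-shaped classification), distance
    probability distributions with peak finding, Kabsch superposition and
    per-residue root-mean-square fluctuations, and pairwise Coulomb and
    Lennard-Jones energy totals. Includes a seeded synthetic-trajectory
    generator with ground-truth manifests for end-to-end validation, and a
    config-driven two-system comparison pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), bio3d, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
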