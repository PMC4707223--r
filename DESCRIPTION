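Package: pepcoord
Title: Atomic Pair-Correlation and Coordination Analysis of Peptide Variants
Version: 0.1.0
Authors@R:
    person("pepcoord", "developers", email = "pepcoord@example.org",
           role = c("aut", "cre"))
Description: Computes total and species-pair partial pair distribution
    functions g(r), radial distribution functions R(r) and cumulative
    coordination numbers from peptide (and peptide-MHC-TCR) tertiary
    structures in PDB format.  Expresses each variant peptide's cumulative
    coordination as a running difference against an index (native) peptide,
    decomposes that difference into backbone/side-chain residue-interaction
    groups over a short-range-order window (default 5-7 Angstrom), and
    classifies variants as over-coordinated (agonist-like) or
    under-coordinated (antagonist-like).  Includes deterministic geometric
    protonation of crystal structures, short-range-order cluster statistics,
    a seeded synthetic-structure generator for validation, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
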