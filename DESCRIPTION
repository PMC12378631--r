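Package: contactsar
Title: Contact-Occupancy Fingerprints and PLS Structure-Activity Analysis
    from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns protein-ligand molecular dynamics trajectories and measured
    potencies into ranked per-residue contact importances. Enumerates candidate
    ligand-residue heavy-atom contacts, filters them to hydrogen-bond-capable
    pairs and aromatic ring pi-stacking candidates, collapses chemically
    equivalent distances (carboxylate oxygens to the carboxyl carbon, arginine
    guanidinium nitrogens to CZ), converts distance time series into
    percent-of-trajectory contact occupancies, and fits a partial least squares
    (PLS1/NIPALS) regression of pIC50 on the occupancy fingerprint. Includes a
    ligand registry with Hill-notation formula parsing and monoisotopic [M+H]+
    masses, a multi-model PDB reader/writer, and a synthetic protein-ligand
    complex generator with programmable two-state contact dynamics and a known
    occupancy-to-potency model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
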