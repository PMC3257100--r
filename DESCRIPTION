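Package: wrndock
Title: Weighted Residue-Network Scoring for Protein-Protein Docking Decoys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and ranks protein-protein docking decoys with a weighted
    residue contact network. Each residue is coarse-grained to its side-chain
    geometric centre; residue pairs closer than a distance cutoff are linked,
    with the magnitude of the Miyazawa-Jernigan inter-residue contact energy as
    the link weight and a fixed weight for peptide-bonded neighbours. The score
    is the negated product of the whole-network strength and the weighted
    average nearest-neighbours degree, so that near-native decoys rank ahead.
    Includes ligand-RMSD evaluation against a native complex, hit calling,
    per-system ranking indicators, success-rate curves with a random-ranking
    baseline, and seeded generators for synthetic complexes and decoy sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
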