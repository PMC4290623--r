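Package: homopharma
Title: Conserved Protein-Ligand Binding Environments from Interaction Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies groups of protein-ligand complexes that share a conserved
    binding environment, topologically similar compounds, and similar
    conservation-weighted interaction profiles ("Homopharma" groups). Provides
    rigid-body (Kabsch) superposition with an RMSD reservation filter, Carhart
    atom-pair topology fingerprints with multiset Tanimoto similarity, geometric
    typing of protein-ligand contacts (electrostatic, hydrogen bond, van der
    Waals; main chain and side chain separately) over multiple-sequence-alignment
    columns, conservation-weighted Tanimoto scoring of interaction profiles,
    two-way hierarchical clustering into groups, and a benchmark module with
    precision/recall/F-measure sweeps and ROC curves. Includes a deterministic
    synthetic-fixture generator for planted binding pockets, compound families,
    and group-recovery scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
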