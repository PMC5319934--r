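Package: ppb
Title: Ligand-Based Polypharmacology Target Prediction by
    Multi-Fingerprint Nearest-Neighbor Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the likely protein targets of a small molecule by
    nearest-neighbor search against a reference database of
    target-annotated bioactive compounds. Six complementary molecular
    fingerprints (atom-pair shape, category atom-pair pharmacophore,
    molecular quantum numbers, SMILES character counts, Daylight-type
    substructure paths, extended-connectivity circular) and four fused
    fingerprints compare molecules by city-block distance; per-fingerprint
    distance modes are matched by scaling before fusion. Observed
    query-to-target distances are converted to p-values via negative
    binomial null distributions fitted to random background pairs, and
    per-fingerprint target lists are merged by consensus voting. Includes
    a reference-database builder for ChEMBL-style activity tables,
    virtual-screening validation metrics (target recovery, hit rate,
    top-5 success, ROC AUC, enrichment factors), a seeded synthetic
    fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
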