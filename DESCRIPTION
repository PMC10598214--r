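Package: pepprior
Title: Interface Prediction and Guide-Peptide Prioritization from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds per-residue protein binding-site labels from linear-peptide
    energy scans, trains a per-position interface classifier on sequence
    embeddings, and cuts ranked fixed-length guide-peptide candidates from the
    predicted interface-probability curves of interacting partner proteins.
    Includes homology-aware dataset splitting by connected-component clustering,
    interactome filtering under stringent and lenient evidence policies,
    evaluation metrics (AUROC, Spearman correlation against per-position
    energies, top-n energy summaries), and seeded synthetic-data generators so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
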