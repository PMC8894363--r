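Package: solcure
Title: Curation of Multi-Source Aqueous Solubility (LogS) Datasets
Version: 0.1.0
Authors@R: person("solcure", "maintainers", email = "solcure@example.org",
    role = c("aut", "cre"))
Description: Tools for turning noisy, multi-source aqueous solubility
    collections (SMILES, LogS) into a single weighted, curated dataset
    ready for property-prediction model training. Implements SMILES
    standardization via RDKit, experiment-environment and heavy-metal
    filtering, within-dataset repetitive-record normalization,
    inter-dataset redundancy matrices, schedule-constrained cross-dataset
    partial clustering of weighted solubility values, weighted evaluation
    metrics (weighted RMSE, Pearson r-squared, Spearman rank correlation),
    random and Bemis-Murcko scaffold data splitting, and a synthetic
    multi-dataset generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the rdkit package on PATH
Config/testthat/edition: 3
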