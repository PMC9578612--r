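Package: dscn
Title: Double-Target Selection Guided by CRISPR Screening and Networks
Version: 0.1.0
Authors@R: person("DSCN", "Maintainers", email = "dscn@example.org", role = c("aut", "cre"))
Description: Selects candidate synthetic-lethal target combinations for cancer
    by integrating tumor-tissue expression, cell-line expression, and CRISPR
    gene-essentiality screens on a shared protein-protein interaction skeleton.
    Tissue and cell-line networks are built with correlation edge weights and
    fold-change or essentiality node weights, spectrally clustered into
    subnetworks, and drug targets are scored with most-probable-path,
    random-walk, or diffusion-path impact scores. First-target knockdown is
    modeled by subsampling cell lines, giving a conditional second-target score
    and an additive pair score; ranked pairs can be tested for association with
    observed drug-combination synergy (Bliss scores). Includes a per-sample
    variant (DSCNi) and a synthetic-data generator with planted cluster and
    synthetic-lethal structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
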