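Package: neomsn
Title: Morphometric Similarity Networks for the Neonatal Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-subject morphometric similarity networks (MSNs) from
    regional multi-modal MRI metrics (structural, diffusion kurtosis and NODDI
    measures over a dHCP-compatible 81-region neonatal parcellation), and uses
    their edges in cross-validated predictive models: elastic-net regression of
    postmenstrual age at scan and linear support-vector classification of term
    versus preterm birth with recursive feature elimination. Includes greedy
    backward elimination over metric subsets, permutation-based significance
    testing, stability-based edge selection, hemisphere-asymmetry tests based
    on homotopic region swapping, and a synthetic cohort generator that
    reproduces the tissue-block correlation structure and confound structure
    the analysis assumes, so the full pipeline is testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
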