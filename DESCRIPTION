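Package: dsim
Title: Multi-Source Disease Similarity Networks and Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes disease-disease similarity by integrating several
    disease-association corpora. Per-source similarity networks are built with
    Lin's information-content measure over a MeSH-style disease DAG, integrated
    into low-dimensional node embeddings via random-walk-with-restart diffusion
    states and a KL-divergence softmax model (diffusion component analysis,
    fitted by truncated SVD or L-BFGS), and disease pairs are scored by cosine
    similarity of the embeddings. Includes a benchmark evaluation protocol
    (AUC and confusion-matrix metrics, dimension sweeps, source ablations,
    category contrasts, top-k recovery) and a synthetic-data generator with
    planted disease clusters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
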