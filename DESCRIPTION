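Package: odieu
Title: Benchmarking and Generating Natural-Language Odor Descriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how close machine-generated free-form odor
    descriptions come to human inter-observer consensus. Provides a data model
    for multi-source odor-description catalogues with cross-source pair
    enumeration, model-free lexical similarity metrics (BLEU, ROUGE-L, METEOR,
    BERTScore), a sentence-embedding benchmark (cosine-similarity
    distributions against shuffled nulls, 1-D earth-mover distance, top-k
    retrieval) with contrastive fine-tuning of trainable embedders,
    representational comparison of perceptual odor spaces (metric MDS,
    canonical correlation analysis, cross-space predictive linear maps),
    structure-to-text generation by prefix-tuning a frozen causal language
    model, and Procrustes alignment of neural population responses into
    invertible sentence-embedding spaces for neural-to-text decoding. A seeded
    synthetic-data generator with known latent structure makes every stage
    testable without licensed odor datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ChemmineOB,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
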