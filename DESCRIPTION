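Package: ehrtraj
Title: Multimodal Transformer Modelling of Electronic Health Record
    Patient Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models longitudinal electronic health records as token
    sequences for breast-cancer prognosis. Provides clinical feature
    engineering (dynamic Nottingham Prognostic Index, biological marker
    binarization and delta tokens, inter-visit delay buckets), tokenization
    of patient trajectories into aligned token/modality/delay/position
    layers, masked-language-model pretraining of a small transformer
    encoder written in pure R, free-text report trajectories via pooled
    token embeddings, fine-tuned tabular and text sequence classifiers
    with class-balanced sampling, cross-attention fusion of the two
    modalities, integrated-gradients attribution with frequent-phrase
    mining and Kaplan-Meier/log-rank validation, evaluation utilities
    (AUC with bootstrap intervals, average precision, DeLong test), and a
    synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
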