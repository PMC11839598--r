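Package: metaug
Title: Targeted Paraphrase Augmentation for Longitudinal Radiology-Report Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying targeted generative data augmentation in
    patient-level metastasis detection from free-text radiology report
    impressions. Provides a seeded synthetic longitudinal corpus generator,
    a deterministic rule-based paraphrase engine with a prompt-builder
    contract for external large language models, four augmentation
    strategies (vanilla, length filtering, k-fold misclassification
    mining, minority-class replication), composition of synthetic patient
    timelines, a hierarchical classifier (text encoder, down-projection,
    one-directional LSTM, causal multi-head attention) with LoRA and deep
    prompt-tuning adaptation on a small in-repo transformer, a
    budget-matched training protocol with early stopping on validation F1,
    and evaluation utilities (multi-seed sweeps, history-window
    truncation, self-BLEU and cosine-similarity diversity metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
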