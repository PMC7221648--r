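Package: charsumm
Title: Character-Level Transformer Extractive Summarization for Clinical Diagnoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extractive summarization of free-text hospital discharge
    diagnoses using a small character-level Transformer encoder trained in
    two stages: masked-character language-model pretraining with
    class-preserving corruption, followed by supervised per-character
    selection fine-tuning. Includes a 100-symbol character tokenizer, a
    synthetic discharge-diagnosis corpus generator with rule-derived
    highlight labels, stitching and typo-injection augmentation, a
    word-average probability cleanup step that prevents fragmented words,
    threshold calibration by F1 on a validation set, and a ROUGE-1/2/L and
    ROC/AUROC evaluation harness. The network (embeddings, multi-head
    self-attention encoder, masked-LM and selection heads, Adam training)
    is implemented in base R matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
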