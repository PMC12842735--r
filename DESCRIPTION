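Package: mdeimplant
Title: Masked Deep Embedding Pre-Training and Two-Stage Dental Implant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised pre-training of vision-transformer backbones for
    dental radiograph analysis using Masked Deep Embedding (MDE): a masked
    autoencoder whose decoder predicts the deep patch embeddings of masked
    patches under an L1 loss, instead of reconstructing pixels.  Includes the
    classic pixel-space masked-autoencoder objective as a baseline, a
    two-stage implant detection pipeline (design-part detection with a dense
    anchor-free head, then geometric assembly of whole-implant bounding boxes
    via k-means++ grouping with missing-part inference), COCO-style average
    precision evaluation with patient-level cross-validation, and a synthetic
    radiograph generator that emulates implant design taxonomies so the whole
    pipeline is testable end-to-end on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
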