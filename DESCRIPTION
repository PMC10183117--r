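Package: spikeCAM
Title: Grad-CAM Interpretive Analysis of Multi-Scale Wheat Spike Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies what each detection layer of a multi-scale
    convolutional object detector attends to in wheat spike (head)
    imagery. Computes gradient-weighted class activation maps (Grad-CAM)
    per detection layer, scores every labeled spike by the fraction of
    its bounding box covered by the layer's attention area, aggregates
    the scores into per-layer bin tables and zero-score audits, and
    turns those statistics into rule-based layer-refinement advice
    (remove, keep, enhance, add a micro-scale companion). Includes a
    fully hand-implemented toy multi-scale detector (forward and
    backward passes) for end-to-end testing, a synthetic labeled-scene
    generator emulating the spike-size diversity of multi-site wheat
    phenotyping datasets, IoU-based detection matching with
    precision/recall/average-precision evaluation, and readers/writers
    for the common annotation formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'conv.R'
    'toyDetector.R'
    'arrayFiles.R'
    'gradcam.R'
    'attention.R'
    'layerStats.R'
    'advisor.R'
    'metrics.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
    'cli.R'
    'utils.R'
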