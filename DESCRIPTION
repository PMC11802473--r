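Package: camil
Title: Channel-Attention Multiple Instance Learning for Whole-Slide Feature Bags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates a transformer-based multiple instance
    learning (MIL) classifier for gigapixel whole-slide images represented as
    bags of patch feature vectors. The aggregator interleaves
    linear-complexity Nystrom self-attention with a multi-scale channel
    attention block (dual depth-wise separable convolution branches and a
    shared-MLP channel gate with temperature sigmoid) that doubles as an
    implicit positional encoding, and pools instances with gated attention
    into a slide-level prediction. Includes a reverse-mode automatic
    differentiation core, a synthetic bag generator with known witness
    instances, patient-safe data splitting, MIL metrics (accuracy, F1, AUC),
    attention-score export for heatmaps, and ablation runners for kernel
    sizes, token order and pooling strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
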