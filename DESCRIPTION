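Package: lemunet
Title: Edge-Guided 3D Multimodal Segmentation of Focal Cortical Dysplasia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A self-contained implementation of an edge-guided 3D encoder-decoder
    segmentation network for focal cortical dysplasia (FCD) lesions in multimodal
    brain imaging (T1, FLAIR, FDG-PET), together with the evaluation methodology
    used in FCD studies. Provides 3D Gaussian/Laplacian pyramids, a MedNeXt-style
    ConvNeXt backbone with deep supervision, Laplacian edge attention (CBAM gated
    mixing of a dedicated T1 encoding branch), multi-strategy feature fusion at the
    last two decoder layers, a combined Dice + cross-entropy deep-supervision loss
    with AdamW training, overlap metrics (Dice, precision, recall, IoU), HD95
    surface distance, 26-connectivity lesion cluster statistics, detection rates at
    Dice thresholds 0.0 and 0.22, largest-component post-processing, NIfTI I/O with
    nnU-Net-style preprocessing, and a synthetic multimodal lesion phantom
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
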