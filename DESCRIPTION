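Package: glioseg
Title: Bayesian 3D Segmentation of Glioma Follow-Up MRI with Uncertainty-Guided Relabeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric Bayesian encoder-decoder segmentation of glioblastoma
    follow-up MRI into FLAIR-hyperintense (FHR), enhancing (ER) and
    non-enhancing necrotic (NENR) subregions. Provides a 3D U-Net with
    variational (Flipout-style) decoder convolutions trained with a
    generalized Dice focal loss plus Kullback-Leibler weight penalty,
    dual-branch transfer-learning fusion for the rare NENR class,
    Monte-Carlo posterior sampling with a background-threshold voxel
    relabeling rule, a full overlap/calibration/selective-prediction
    evaluation suite, and a multi-modal brain phantom generator so the whole
    pipeline is exercisable end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
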