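Package: patchSDM
Title: Joint Species Distribution Modelling from Environmental Patch Tensors
Version: 0.1.0
Authors@R: person("SDM", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Presence-only joint species distribution modelling from
    multi-resolution environmental raster patches. Provides raster stack
    handling with categorical one-hot expansion and sentinel filling of
    undefined pixels, extraction of environmental tensors and punctual
    vectors at occurrence points, a convolutional neural network predicting
    a categorical distribution over species, punctual baselines (a
    constant-tensor deep network, random forest and boosted trees), an
    ablation suite that degrades landscape spatial structure in the input
    tensors, set-valued top-k accuracy metrics with per-species averaging,
    weighted pseudo-absence sampling for AUC and TSS, activation-map
    rendering, and a synthetic landscape and occurrence simulator so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
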