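Package: attnmod
Title: ROI-Based Analysis of Endogenous and Exogenous Covert Spatial
    Attention in Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ROI-based event-related fMRI analysis of covert
    spatial attention: randomized 2-AFC cueing designs with pre- and
    post-cues, a simulated psychophysical observer with staircase
    titration and d-prime/reaction-time summaries, synthetic BOLD
    time-series generation (event-related attention runs and
    block-design localizers) with known ground-truth condition
    amplitudes, sinusoid-fit coherence-based voxel selection,
    twelve-regressor GLM amplitude estimation in percent signal change,
    the Attentional Modulation Index (AMI), and group-level inference
    across the visual hierarchy (per-ROI tests, hierarchy regressions,
    repeated-measures ANOVAs and linear mixed models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
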