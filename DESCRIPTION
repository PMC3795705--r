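Package: discdiff
Title: Post-Contrast MRI Quantification of Contrast Agent Transport in
    Intervertebral Discs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gadolinium contrast agent transport into
    lumbar intervertebral discs from serial post-contrast T1-weighted MRI.
    Implements landmark-based layered segmentation of the disc into
    subchondral bone, endplate-zone, peripheral and central regions of
    interest, per-ROI enhancement (post minus pre contrast signal) across a
    six-point acquisition schedule, CSF-adjusted T2-weighted signal intensity
    as a continuous hydration index, and the nonparametric cohort statistics
    used in post-contrast disc studies (rank-sum, Kruskal-Wallis with Dunn's
    multiple comparisons, Spearman correlation, univariate analysis of
    variance). A synthetic spine phantom with a one-dimensional
    diffusion-perfusion model of contrast kinetics provides ground-truth
    data so that the whole pipeline is testable without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
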