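Package: avmvpa
Title: Simulation and Multivoxel Pattern Analysis of Audiovisual fMRI
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic event-related BOLD fMRI data for an
    audiovisual experiment (four stimuli crossed with audiovisual
    congruent, incongruent, visual-only and auditory-only conditions)
    and analyses it with the standard multivoxel pattern analysis
    toolchain: run-wise trial general linear models with a canonical
    double-gamma haemodynamic response, four-way stimulus decoding via
    six pairwise linear support vector machines with one-against-one
    voting and leave-one-run-out cross-validation, split-half pattern
    reliability and inter-stimulus pattern similarity (Fisher-z
    correlations), region-of-interest mean amplitudes, whole-volume
    searchlight information mapping with sign-flip permutation cluster
    inference, phase-encoded retinotopic mapping analysis, and the
    group-level repeated-measures statistics used to compare them. The
    generative model holds the stimulus-specific pattern templates and
    the mean signal amplitude constant across conditions while letting
    the trial-to-trial pattern noise depend on condition, so that
    decodability and pattern reliability can dissociate from signal
    amplitude.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
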