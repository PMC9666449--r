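Package: tusvep
Title: Analysis of Transcranial Ultrasound Neuromodulation of Visual Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of transcranial focused ultrasound (TUS)
    neuromodulation experiments targeting the visual thalamus: simulation of
    multi-electrode EEG with a configurable evoked-response suppression,
    band-pass filtering, epoching, artifact rejection and ICA component
    cleaning, N70/P100 visual evoked potential quantification with baseline
    normalization and laterality indices, Morlet-wavelet decomposition of
    total, phase-locked and non-phase-locked power with permutation
    difference-map statistics, MR acoustic radiation force imaging (MR-ARFI)
    displacement mapping from paired phase images, sonication dose arithmetic
    (duty cycles, I_SPTA), and a finite-difference Pennes bioheat solver for
    temperature-rise estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    RNifti,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
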