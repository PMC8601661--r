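Package: fusnatsynth
Title: Denoising and Model-Matched Sound Analysis for Functional Ultrasound Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for analysing trial-structured hemodynamic imaging
    responses (functional ultrasound or fMRI-like) to natural sounds and
    statistics-matched synthetic sounds. Provides a synthetic-data generator
    with known latent components and structured noise; power-Doppler image
    formation with SVD clutter filtering; baseline normalisation and
    time-window averaging; canonical-correlation scrubbing of noise shared
    with out-of-cortex voxels; reliability-biased component denoising
    (denoising source separation) with cross-validated component-count
    selection; the normalized squared error (NSE) dissimilarity statistic and
    its noise-corrected variants; histogram-entropy component decomposition
    with cross-species ridge prediction; cochleagram and modulation-energy
    acoustic features with a max-statistic permutation test; and spatial
    profiling (surface projection, annular distance profiles, slope
    contrasts, category difference maps, video motion index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
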