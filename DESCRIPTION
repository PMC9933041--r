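Package: dosytools
Title: Simulation, Processing and Fitting of Diffusion-Ordered NMR (DOSY)
    Experiments for Metabolic Phenotyping
Version: 0.1.0
Authors@R:
    person("Nikita", "Developer", email = "dosytools@example.org",
           role = c("aut", "cre"))
Description: A toolkit for diffusion-ordered NMR spectroscopy (DOSY) of
    biofluids. Provides forward models of three optimized DOSY pulse
    sequences (a traditional bipolar-LED experiment, a relaxation-edited
    double spin-echo train, and a diffusion-edited long-delay variant),
    a synthetic biofluid phantom simulator producing pseudo-2D
    gradient-incremented datasets with known ground truth, spectral
    processing (Gaussian apodization, Fourier transform, automatic
    phasing, chemical-shift calibration, water pruning, noise
    estimation), Stejskal-Tanner diffusion-coefficient fitting with peak
    picking, pulsed-field-gradient calibration against a doped-water
    reference, and a multi-spectrum peak-list filtering tool with CSV
    export.  A command-line interface orchestrates the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
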