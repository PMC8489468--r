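Package: quickdwi
Title: Simulation, Deep-Learning Denoising, and ADC Quantification for
    Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("quickdwi", "developers", email = "quickdwi@example.org",
           role = c("aut", "cre"))
Description: Tools for accelerated diffusion-weighted MRI (DWI). Simulates
    multi-b-value DWI phantoms with known S0 and apparent diffusion
    coefficient (ADC) maps, reproduces the clinical acquisition-averaging
    chain (Rician-noised single acquisitions, trace-weighted geometric
    averaging over diffusion directions, arithmetic averaging over repeats),
    trains a U-Net style convolutional denoising image filter that maps
    single-acquisition images to clinical-standard averaged images, fits
    monoexponential ADC maps by least squares, and evaluates image quality
    (MSE, SSIM, PSNR) with paired Wilcoxon / Benjamini-Hochberg statistics.
    Includes a command-line interface and minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
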