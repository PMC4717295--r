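Package: asfnet
Title: Area Summation and Population Coding Efficiency in a Spiking Model of
    Early Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking the non-linear area summation function
    (ASF) of primary visual cortex neurons to the efficiency of the population
    code. Grayscale images are converted to broad-band contrast-energy fields
    with a Gabor filter bank, filtered through a midget-cell retina model onto
    a retinotopic cortical sheet, and fed to a recurrent exponential
    integrate-and-fire spiking network whose lateral and feedforward-feedback
    connectivity is swept over a logarithmic grid. Per-neuron target
    activation patterns are predicted from a ratio-of-Gaussians area summation
    model, and the distance between simulated and target patterns (DAS) is
    correlated with spike-count energy use, entropy per spike, and population
    sparseness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    Rcpp,
    EBImage,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
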