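Package: fwnndmp
Title: Fuzzy Wavelet Neural Network and Kinetic Modelling of Dimethyl
    Phthalate Biodegradation in A/A/O Wastewater Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the removal of dimethyl phthalate (DMP) in an
    anaerobic/anoxic/oxic (A/A/O) activated-sludge process by two routes: a
    Takagi-Sugeno-style fuzzy wavelet neural network (Gaussian antecedents,
    Mexican-hat wavelet consequents) trained by a hybrid real-coded genetic
    algorithm plus gradient descent, and an ASM2-derived hydrolysis model
    (Monod rate law with redox switching functions, double-reciprocal
    linearised fitting of the maximum rate, half-saturation constant and
    zone reduction factors). Includes a synthetic A/A/O dataset generator,
    an evaluation harness (R2, MAPE, RMSE, MSE), a three-model comparison
    workflow, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
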