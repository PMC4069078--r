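Package: nmrdyn
Title: Backbone Dynamics of Proteins from NMR Relaxation, H/D Exchange
    and Residual Dipolar Couplings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for protein backbone dynamics from solution
    NMR observables: exponential fitting of 15N R1/R2 relaxation decays with
    jackknife uncertainties, heteronuclear NOE ratios, rotational diffusion
    estimation (local and global correlation times, axially symmetric tensor,
    inertia moments, viscosity/temperature extrapolation and theoretical
    correlation-time estimates), Lipari-Szabo model-free fitting with model
    selection and Monte Carlo errors, conformational-entropy accounting from
    order parameters, hydrogen/deuterium exchange kinetics with intrinsic
    rates and protection factors, structure-ensemble superposition and RMSD
    statistics, N-H bond vector extraction, and residual dipolar coupling
    quantification with alignment-tensor fitting. A synthetic-data generator
    produces ground-truth parameter sets and noisy observations with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without spectrometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
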