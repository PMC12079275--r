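Package: protoelec
Title: Electrical Dynamics of Proteinoid-Actin Protocell Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the bioelectricity of proteinoid microspheres,
    actin filament networks and their mixtures. Implements equivalent-circuit
    modelling and complex nonlinear least-squares fitting of electrochemical
    impedance spectra (resistor, capacitor, constant-phase, semi-infinite and
    finite-length Warburg elements), conductivity derivation from impedance
    magnitude and cell geometry, multichannel membrane-potential spike detection
    and oscillation statistics, excitability classification, square-wave
    stimulation-response characterisation, current-voltage cycling memory-effect
    analysis, temperature-pH coupling analysis (dominant periods, phase lag,
    spectral coherence, Arrhenius protonation kinetics), and a
    capacitance-modulated Gray-Scott reaction-diffusion simulator for Turing
    pattern formation. A synthetic-data module generates every input modality
    with controlled statistical structure so all analysis stages are testable
    end to end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
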