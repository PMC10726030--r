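Package: sednp
Title: Slow-Motional EPR and Solid-Effect DNP Spectra of Tumbling Radicals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates continuous-wave EPR spectra and solid-effect/Overhauser
    dynamic nuclear polarization (DNP) enhancement profiles for slowly tumbling
    polarizing agents with anisotropic g tensors in viscous liquids. The
    stochastic Liouville equation for isotropic rotational diffusion is expanded
    in Wigner rotation functions, microwave saturation and dispersion admixture
    are treated exactly, and the translational modulation of the electron-nucleus
    dipolar coupling is described by the force-free hard-sphere spectral density
    evaluated at a matrix argument. Includes least-squares fitting of derivative
    EPR spectra and DNP field profiles, decomposition of mixed DNP spectra into
    their Overhauser and solid-effect components, and derivation of molecular
    parameters (coupling factor, contact distance, diffusion coefficient) from
    the fitted amplitudes.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
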