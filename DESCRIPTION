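Package: vesana
Title: Scattering and Calorimetry Analysis of Lipid Vesicle Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for temperature-dependent studies of small
    unilamellar lipid vesicles and their interaction with membrane-active
    additives. Covers differential scanning calorimetry peak deconvolution
    (phase-transition temperatures by Lorentzian fitting), wide-angle X-ray
    scattering chain-chain correlation distances, indirect Fourier
    transformation of small-angle scattering curves to the pair-distance
    distribution function and radius of gyration, modified Kratky-Porod
    membrane thickness, lamellar Bragg-peak analysis, and multi-angle photon
    correlation spectroscopy (regularized inverse Laplace inversion,
    diffusion fits and Stokes-Einstein hydrodynamic radii). A seeded
    synthetic-data module generates all four data types, with presets
    encoding a DMPC-naproxen-aescin composition series, so every stage of
    the chain can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    ggplot2,
    splines,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
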