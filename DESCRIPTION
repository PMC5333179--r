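Package: fluortrace
Title: Spectral Monte Carlo Path Tracing of Fluorescent Scattering Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physically-based rendering of fluorescent-tagged, highly
    scattering volumetric media for virtual fluorescence microscopy.
    Implements a spectral Monte Carlo path tracer with a fluorescence-aware
    path integral (woodcock tracking in labeled voxel volumes, Henyey-
    Greenstein phase sampling, next-event light sampling at the single
    inelastic vertex), fluorophore models built from excitation/emission
    spectra, quantum yield and molar absorptivity, a procedural generator
    of neuron-like tissue blocks (morphologies, watertight capsule meshes,
    solid voxelization), and spectral-power-distribution validation tools
    (emission-profile comparison and excitation-wavelength scans).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
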