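Package: vqspect
Title: Desk-Scale Simulation of Dual-Isotope Lung V/Q SPECT with Ground-Truth Perfusion Defects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, deterministic simulator for dual-isotope lung
    ventilation/perfusion (V/Q) SPECT. Builds tissue-coded digital thorax
    phantoms from CT Hounsfield-unit volumes (or a bundled parametric
    synthetic thorax), paints Kr-81m ventilation and Tc-99m-MAA perfusion
    source maps including the gravity-driven anterior-to-posterior
    perfusion gradient over sixteen coronal planes, simulates energy-window
    SPECT acquisitions with attenuation, distance-dependent collimator
    response, scatter and Kr-to-Tc downscatter, reconstructs with ordered
    subsets expectation maximization (OSEM) with optional attenuation and
    dual-energy-window scatter correction, and validates reconstructions
    voxelwise against a (synthetic) normal database via Z-score maps.
    Perfusion defects are inserted with exact ground truth, including the
    pulmonary vascular obstruction index (PVOI), for benchmarking
    functional-lung delineation methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
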