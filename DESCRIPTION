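Package: triaxmeg
Title: Simulation and Analysis of Triaxial OPM Magnetoencephalography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing magnetoencephalography (MEG)
    recordings from wearable arrays of triaxial optically pumped magnetometers
    (OPMs). Includes construction of helmet sensor arrays with rigid-body
    motion, an analytic current-dipole forward model in a spherical conductor,
    a quasi-static background-field model with spherical-harmonic (uniform +
    linear gradient) nulling via simulated biplanar coils, a Lorentzian
    zero-field-resonance model of OPM gain error, dynamic field stabilization,
    a synthetic-paradigm generator with planted beta-band desynchronization,
    rebound and envelope-coupling structure, LCMV beamforming with optimal
    source orientation and pseudo-T imaging in triaxial or radial-only mode,
    amplitude-envelope-correlation connectomics with pairwise leakage
    orthogonalization, and repeatability ("fingerprinting") statistics based
    on rank-sum and permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
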