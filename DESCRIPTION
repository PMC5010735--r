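Package: runtumble
Title: Run-and-Tumble Analysis of In Vivo Cell Migration Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying directional persistence of cell migration
    from 3D tracking data. Segments trajectories into run and tumble phases
    with an unbiased threshold derived from the joint probability density of
    a local alignment index and scaled speed, computes per-phase summary
    statistics (durations, speeds, inter-run angles, persistence), quantifies
    protrusion orientation via the polar order parameter, simulates
    run-and-tumble active Brownian particles pursuing a moving target,
    calibrates the simulator against measured summary statistics, and
    evaluates migration precision through positional dispersion of cell
    groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lhs
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
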