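Package: itpk
Title: Distributed Mechanistic Pharmacokinetics of Intrathecal Drug Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spatiotemporal pharmacokinetics of intrathecally
    administered therapeutics (such as antisense oligonucleotides) along the
    neuraxis. The spinal cerebrospinal fluid is modelled as a one-dimensional
    advection-dispersion-reaction channel coupled to a distributed spinal-tissue
    rod and lumped cranial CSF, cranial tissue, blood and peripheral
    compartments. Provides infusion scheduling with distributed point-spread
    sources and plug-flow velocity fields, a finite-volume method-of-lines
    solver, brain-region partitioning, exposure and PK summary observables,
    infusion-regimen sweeps, synthetic-data generation and least-squares
    parameter calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
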