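Package: kneeload
Title: Knee Force Distribution by Static Optimization over the Gait Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Distributes the intersegmental resultant force and moment at the
    knee joint center among twelve muscles, four ligaments (ACL, PCL, MCL,
    LCL) and the two tibiofemoral contacts, frame by frame over the gait
    cycle, by constrained static optimization. Three problem formulations are
    supported (moment equipollence with muscles and contacts; moment
    equipollence with ligaments added; simultaneous force and moment
    equipollence) together with eight optimization criteria (sums and maxima
    of muscle forces and muscle stresses, with linear, quadratic and cubic
    powers). Includes a synthetic gait-trial generator with flexion-dependent
    structure geometry, diagnostics (unbalanced force vectors, total ligament
    force, per-axis RMS over the gait cycle, contact-force peaks in body
    weight), CSV/YAML interfaces and a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
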