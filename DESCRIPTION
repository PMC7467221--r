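Package: corticalwaves
Title: Traveling-Wave Models of Direction-Selective Motion Discrimination
    in Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wilson-Cowan neural mass and 1-D neural field models of
    direction-selective motion discrimination by endogenous traveling
    waves in primary visual cortex. Implements the point E-I and opponent
    E-I-E (two excitatory populations sharing one inhibitory pool)
    models, their spatially extended counterparts with shifted-Gaussian
    lateral coupling on a periodic domain, drifting-grating stimulation,
    pseudo-arclength equilibrium continuation with Hopf, branch-point and
    limit-point detection, seeded winner-take-all trial ensembles, and
    spatiotemporal spectral analysis and tuning curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
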