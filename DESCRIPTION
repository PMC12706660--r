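Package: lvadflow
Title: Lumped-Parameter Hemodynamics of LVAD Cannulation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transient zero-dimensional (lumped-parameter) simulation of the
    systemic arterial tree under extracorporeal left ventricular assist device
    (LVAD) support, for comparing axillary versus femoral arterial perfusion.
    Builds a resistance-inertance network of the aorta and its fifteen major
    branch outlets, couples every outlet to a three-element Windkessel model
    implicitly at each time step, calibrates the Windkessel parameters to
    target flow divisions and systolic/diastolic pressures, runs constant-flow
    graft scenarios, and post-processes cycle-averaged flow shares,
    time-averaged wall shear stress (TAWSS) and the oscillatory shear index
    (OSI).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
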