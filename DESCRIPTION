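Package: vdefsim
Title: Airway-Tree Simulation of Bronchoconstriction, Deep Inspirations,
    and Emergent Ventilation Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates bronchoconstriction in a symmetric bifurcating
    airway tree with Weibel-style morphometry. Each airway carries a
    bistable smooth-muscle/wall model driven by its peak transmural
    pressure; radii evolve breath to breath through a recursion with
    separate constriction and dilation speed indexes. A within-breath RC
    network solver delivers per-terminal ventilation and per-airway peak
    transmural pressures; periodic deep inspirations (DIs) are scheduled
    at configurable volume ratios and cycle intervals with matched mean
    ventilation. Outcome measures include the fraction of closed terminal
    units, Mandelbrot-style ventilation maps, 6 Hz input resistance, and
    normalized post-DI resistance responses. Parameter sweeps reproduce
    the two-domain structure of ventilation-defect emergence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
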