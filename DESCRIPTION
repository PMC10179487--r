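Package: sdhkin
Title: Kinetic Modeling of Electron Transfer and ROS Production in
    Mitochondrial Complex II
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic kinetic model of mitochondrial respiratory
    complex II (succinate dehydrogenase / quinol-fumarate reductase):
    a mass-action reaction network over 31 species covering quinol
    oxidation at the Q-site, electron relay through heme b and the three
    iron-sulfur clusters, flavin-site fumarate/succinate chemistry, and
    superoxide/hydrogen-peroxide bypass reactions.  Provides stiff
    steady-state solvers with moiety-conservation elimination,
    Nernst-based construction and detailed-balance validation of
    equilibrium constants, substrate scans with Michaelis-constant and
    turnover-number extraction, ROS flux reporting with unit conversion,
    and monotonicity (tunnel-diode) diagnostics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
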