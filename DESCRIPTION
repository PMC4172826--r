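Package: autophagosim
Title: Agent-Based Simulation of Autophagic Vesicle Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic agent-based simulation of the autophagy pathway in a
    two-dimensional circular cell: phagophores nucleate, mature into
    autophagosomes, fuse with lysosomes into autolysosomes, and are degraded,
    while vesicles move randomly or are transported radially along the
    nucleus-periphery axis. An integrative model variant couples vesicle
    kinetics to a lattice of free and bound nutrients (boundary influx,
    anabolic conversion, lysosomal recycling, autophagosomal uptake,
    autolysosomal release, diffusion), so that nutrient deficit feeds back on
    phagophore and lysosome creation, autolysosomal degradation and lysosomal
    positioning. Includes ensemble runners, a squared-percent-deviation
    fitness function against vesicle count/size reference data, a real-valued
    genetic algorithm for parameter calibration with random-baseline
    comparison, synthetic-reference generation for parameter-recovery tests,
    and CSV/JSON exporters with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
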