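Package: cnspbpk
Title: Physiologically Based Pharmacokinetics of Drug Distribution in the
    Human Central Nervous System
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A compartmental physiologically based pharmacokinetic (PBPK)
    simulator of unbound small-molecule drug disposition in the human central
    nervous system. A fixed one-compartment plasma model drives nine CNS
    compartments (brain microvasculature, brain extracellular and
    intracellular fluid, lysosomes, and the cerebrospinal fluid chain from
    the lateral ventricles to the subarachnoid space) connected by
    paracellular pore-restricted diffusion, pH-dependent transcellular
    permeation, Kp,uu-calibrated active transport asymmetry, and CSF bulk
    flow. Includes non-compartmental summary metrics (Cmax, Tmax, AUC,
    Kp,uu), a what-if scenario engine for pathophysiological changes in
    cerebral blood flow, tight-junction pore radius, brain ECF volume and
    brain ECF/ICF pH, a virtual drug panel generator, and CSV/YAML readers
    and writers for drug tables and physiology sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
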