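Package: hemeET
Title: Ultrafast Photoinduced Electron Transfer Analysis for
    Photosensitizer-Multiheme Cytochrome Biohybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pump-probe transient-absorbance studies of
    Ru(II)(bpy)3 photosensitizers covalently linked to the triheme cytochrome
    PpcA. Corrects time-by-wavelength difference-absorbance matrices for probe
    chirp, coherent solvent response and heme excited-state dynamics; extracts
    the 553-541 nm heme-reduction kinetic trace; fits instrument-response
    convolved sequential charge-separation/charge-recombination schemes and
    compares two-state against multi-state kinetic readings; evaluates Marcus
    nonadiabatic rate ratios for midpoint-potential perturbations; computes
    minimal donor-acceptor aromatic-atom distance distributions from labeled
    multi-model PDB trajectories; and provides Guinier and multi-heme Nernst
    titration fitters. A synthetic-data generator with known ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    minpack.lm,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic-characterization.R'
    'characterization.R'
    'hemeET-package.R'
    'io-ta.R'
    'kinetics.R'
    'marcus.R'
    'synthetic-trajectory.R'
    'trajectory-io.R'
    'trajectory-analysis.R'
    'synthetic-ta.R'
    'ta-processing.R'
    'pipeline.R'
    'utils-conv.R'
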