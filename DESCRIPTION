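Package: rhotraj
Title: Conformational-State and Interaction Analysis of GTPase MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for small-GTPase molecular-dynamics ensembles
    in the style used to dissect constitutively activating RhoA mutants:
    conformational-state classification of the switch regions from the two
    characteristic gamma-phosphate hydrogen bonds, geometric hydrogen-bond
    detection and occupancy statistics, solvent-accessible surface area by the
    LCPO approximation with a Shrake-Rupley numerical oracle, catalytic-site
    water counting, average-linkage conformational clustering on pairwise RMSD,
    RMSD/RMSF fluctuation profiles, a simplified Kabsch-Sander secondary
    structure assignment, and MM/GBSA binding-free-energy bookkeeping.
    Includes a synthetic-trajectory generator that plants Markov state
    sequences, hydrogen-bond geometries, fluctuation amplitudes and
    gamma-phosphate water shells so every analysis stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
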