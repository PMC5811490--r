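Package: pepdisc
Title: Amphipathic Peptide Design Metrics and Lipid Nanodisc Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-level amphipathicity metrics for apolipoprotein A-I
    mimetic peptides (molecular weight, net charge, isoelectric point,
    Wimley-White mean hydrophobicity and hydrophobic moment, helical-wheel
    layout and hydrophobic-face subtended angle, CD-derived helicity),
    together with geometry builders for synthetic membrane, bilayer-edge and
    nanodisc configurations and the trajectory post-processing metrics used
    to characterise peptide-lipid assemblies: insertion height above the C2
    plane, salt-bridge and hydrophobic contact counting with minimum-image
    periodicity, contact lifetimes, dimer orientation and register
    classification, number-density maps, moment-of-inertia disc diameter,
    and block-averaged standard errors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
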