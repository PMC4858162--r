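Package: clampring
Title: Geometry and Coarse-Grained Ring-Opening Dynamics of DNA Sliding Clamps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the ring geometry of DNA sliding clamps
    (bacterial beta clamps, bacteriophage gp45, eukaryotic PCNA) from
    structures and trajectories: per-domain centre-of-mass distances, angles
    and torsions, the signed spiral-handedness sum across an opened
    interface, Kabsch superposition, size-normalised RMSD (RMSD100), and
    inter-domain rotation angles.  Includes a coarse-grained (one bead per
    clamp domain) Langevin dynamics simulator with the three steered
    ring-opening protocols (interface separation, left-handed and
    right-handed spiral torsion steering), a sphere-and-arrow representation
    of domain orientation, and a synthetic clamp/trajectory generator with
    exact ground truth for validation.
License: MIT
Encoding: UTF-8
Imports: bio3d, yaml, Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
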