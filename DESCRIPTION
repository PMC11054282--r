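Package: toykd
Title: Supervised-Binding and Thermal-Titration Molecular Dynamics on Coarse-Grained Pocket Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained re-implementation of two enhanced-sampling molecular
    dynamics protocols used in kinase inhibitor design: supervised molecular
    dynamics (SuMD), which accelerates ligand-binding events by retaining only
    simulation windows in which the ligand approaches the binding site, and
    thermal titration molecular dynamics (TTMD), which ranks protein-ligand
    complex stability by the temperature at which the native interaction
    fingerprint is lost. Includes a synthetic-system generator producing rigid
    pocket models with hinge hydrogen-bond anchors and structural-water sites,
    a switched Coulomb/Lennard-Jones interaction-energy model with per-site
    decomposition, a BAOAB Langevin integrator for the mobile ligand,
    protein-ligand interaction fingerprints with cosine-similarity scoring,
    pharmacophore pose filtering, titration profiles with MS stability
    coefficients, and plain-text readers/writers for systems, trajectories and
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
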