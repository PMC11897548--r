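Package: lh2et
Title: Excitonic Structure and B800-B850 Energy Transfer in the LH2 Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models intra-complex excitation energy transfer in the peripheral
    light-harvesting complex 2 (LH2) of purple bacteria under detergent and
    lipid-membrane (POPC, DOPC) conditions. Builds Frenkel exciton Hamiltonians
    for the 27 bacteriochlorophyll sites from a calibrated C9-symmetric ring
    geometry (or a PDB structure), samples Gaussian static disorder, and
    characterises excitons via energies, transition dipole strengths, the
    l1-norm of coherence and the inverse participation ratio. Computes
    B800-to-B850 transfer-rate distributions with generalized Forster theory
    using second-order cumulant lineshapes, Drude-Lorentz baths with Matsubara
    expansions and modified-Redfield exciton lifetimes, and cross-checks the
    dynamics with a hierarchical-equations-of-motion (HEOM) engine including
    Pauli-fit rate extraction and linear spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
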