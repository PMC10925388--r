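Package: NNPkit
Title: Modular Neural Network Potentials with Physical Priors
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular framework for neural network potentials: composable
    representation models (a Cartesian rank-2 tensor message-passing network,
    an equivariant transformer and an invariant graph convolution network),
    scalar output heads and physics-based prior energies (per-element
    reference energies, switched Coulomb electrostatics, DFT-D2 dispersion
    and Ziegler-Biersack-Littmark screened nuclear repulsion) composed into a
    single model that predicts a per-sample scalar (energy) and, by exact
    differentiation, its negative position gradient (forces). Includes a
    batch-aware neighbor-search engine with open, rectangular and triclinic
    periodic boundary conditions and a padded static-shape contract, a
    reverse-mode automatic-differentiation core supporting the second
    derivatives needed for force-matching training, dataset loaders for NumPy
    and HDF5 conformer collections, a deterministic training loop with
    checkpointing, and a YAML-configured command line surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
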