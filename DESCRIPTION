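Package: funnelscape
Title: Explicit Construction of Protein Folding Free-Energy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds the effective-energy folding landscape f(Q) of a protein
    from an atomistic conformational ensemble: per-frame effective energy
    f(r) = E_u(r) + G_solv(r), the fraction-of-native-contacts order
    parameter Q, Q-binned landscapes with block-analysis errors and funnel
    slope fits, the free-energy profile F(Q) and the configurational-entropy
    profile connecting the two.  For coupled folding and binding it computes
    the solvent-averaged binding potential, its exact per-residue
    site-directed decomposition with neutral/charged group sums, and the
    standard binding free energy assembled from ensemble averages,
    quasi-harmonic configurational entropy and an external (translational
    plus rotational) entropy referenced to the 1 M standard state.  Includes
    seeded synthetic generators (Go-model Monte Carlo chains, slope
    ensembles, two-chain complex fixtures with ground-truth ledgers) and a
    deterministic command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
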