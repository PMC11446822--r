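Package: hexelmap
Title: Receptive-Field Prediction from Connectome Wiring on Hexagonal Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for interpreting dense connectomes of retinotopic circuits.
    Columnar ("hexel") cell types are assigned to a hexagonal lattice of
    columns by weighted linear assignment against an anchored reference type;
    synapse-count matrices are normalized into column-stochastic input
    fractions; mono-, di- and tri-synaptic connectivity maps are built on the
    lattice, aligned, cropped and averaged; receptive-field predictions are
    summarized by covariance ellipses with a uniform-hexagon correction and by
    1D projections along the lattice axes; thresholded, signed type-to-type
    wiring diagrams are extracted and disynaptic pathways ranked by anatomical
    strength. A seeded synthetic-connectome generator with ground truth
    supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
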