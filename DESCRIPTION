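Package: pocketsphere
Title: Spherical Featurization and Graph Convolutional Analysis of Protein Binding Pockets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts protein binding pockets into property-attributed
    spherical feature maps and learns rotation-invariant pocket
    classifications and similarity descriptors with a graph-based spherical
    convolutional network. Pockets are located as clusters of gap spheres
    placed between protein atoms, filtered against the convex hull of
    ligand-proximal atoms, meshed as the solvent-excluded surface of the
    sphere cluster, and attributed with pseudocenter, hydrophobicity and
    electrostatic properties. The attributed surface is ray-cast onto a
    HEALPix pixelization of the sphere to give nine spherical feature maps,
    which feed a hierarchical graph convolutional network with polynomial
    Laplacian filters trained either for multi-class pocket classification
    or for contrastive metric learning of 256-dimensional similarity
    descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    pROC
Config/testthat/edition: 3
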