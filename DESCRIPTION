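Package: mineralfront
Title: Quantification of 3D Bone Mineralization Around the Haversian Canal
    and the Lacunocanalicular Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the spatial progression of bone matrix
    mineralization in 3D backscattered-electron image stacks of forming
    osteons, such as those acquired by FIB-SEM serial surface imaging.
    Implements three-peak gray-value histogram segmentation of embedding
    medium, unmineralized and mineralized matrix; exact 3D Euclidean
    distance transforms from the Haversian canal and the lacunocanalicular
    network (LCN); distance-conditioned gray-value probability
    distributions; mineralized-volume-fraction profiles with 5%/95%
    transition-zone detection; ring-shell statistics of the mineral-poor
    "halo" zone around canaliculi across mineralization stages; and
    detection and morphometry of discrete mineralization foci. A synthetic
    forming-osteon phantom generator with full ground truth supports
    validation of every stage, including emulation of stack drift, noise
    and curtaining artifacts together with the corresponding correction
    operators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
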