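Package: domainseg
Title: Domain Segmentation of Predicted Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses predicted protein structure models (AlphaFold-style) into
    structural domains. Converts inter-residue heavy-atom distances, predicted
    aligned error (PAE) matrices, and homology evidence from sequence and
    structure searches against a classified domain database into per-residue-pair
    same-domain probabilities with a residual dilated convolutional network, then
    converts the probability map into discrete (possibly discontinuous) domain
    definitions via disorder masking, helical-linker detection, greedy segment
    clustering and contact-based boundary refinement. Includes evaluation metrics
    (detection rate, split counts, intersection-over-union) and a synthetic
    fixture generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
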