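Package: pocketgt
Title: Ligand Binding Site Rescoring with an E(3)-Invariant Graph Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid ligand binding site prediction for protein structures.
    Geometric pocket candidates (for example Fpocket alpha-sphere output) are
    converted into residue-level contact graphs with amino-acid and
    solvent-accessible surface area features, and rescored as true or false
    binding sites by a graph transformer with edge-biased attention whose
    score is invariant under rigid rotations, translations and reflections of
    the input coordinates. Includes distance-to-ligand (DCA) labeling,
    imbalance-aware training with label balancing and structured noise
    augmentation, 5-fold cross-validation with ensemble averaging,
    precision-recall and Top-(n+i) evaluation, and a synthetic fixture
    generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
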