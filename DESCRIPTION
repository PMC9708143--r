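Package: forgeNet
Title: Forest Graph-Embedded Deep Feedforward Networks for Compound Activity Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies disease-related compounds with a forest graph-embedded deep
    feedforward network (forgeNet). Molecules given as SMILES are featurized into 208
    classical two-dimensional descriptors plus the 166 MACCS substructure keys (374
    features in total). A decision-tree ensemble fitted to labelled training data is
    mined for a feature graph (edges connect the split feature of a tree node to the
    split features of its internal children), and the graph's adjacency matrix masks
    the first layer of a deep feedforward classifier via a Hadamard product. Includes
    confusion-matrix metrics (sensitivity, specificity, Cohen's kappa, Matthews
    correlation, F1), ROC/PR curves, repeated stratified k-fold and leave-one-out
    cross-validation, activity-based ranking of candidate compounds, and a synthetic
    data generator with graph-structured informative features for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    randomForest,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
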