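Package: ggapACP
Title: Anticancer Peptide Classification from g-Gap Dipeptide Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-based identification of anticancer peptides (ACPs).
    Peptides are encoded as g-gap dipeptide compositions (a pseudo amino acid
    composition instantiation retaining partial sequence order), features are
    ranked by one-way ANOVA F-value and pruned by incremental feature
    selection, and classification uses a soft-margin support vector machine
    with a radial basis function kernel. Evaluation follows the jackknife,
    k-fold cross-validation and independent-set protocols with sensitivity,
    specificity, overall accuracy and the Matthews correlation coefficient in
    the confusion-count parameterization. A synthetic peptide generator with
    controllable class-discriminating structure supports testing and
    benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Classification, Proteomics, FeatureExtraction, SupportVectorMachine
RoxygenNote: 7.3.3
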