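Package: crproles
Title: Predicting Activator and Repressor Roles of CRP from Binding-Site Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting whether the cyclic AMP receptor protein (CRP)
    of Escherichia coli activates or represses transcription at a given binding
    site. Implements curation of RegulonDB-style binding-site tables on a
    TSS-relative coordinate axis, a 380-feature sequence descriptor (k-mer
    composition, promoter-window overlaps, physicochemical and global sequence
    features), wrapper feature selection with an inheritable bi-objective
    combinatorial genetic algorithm around an RBF support vector machine,
    C4.5-style gain-ratio decision trees with rule extraction, the canonical
    four-rule activation/repression classifier with coverage statistics,
    consensus-sequence screening of candidate sites, confusion-matrix and ROC
    evaluation with repressor as the positive class, and a synthetic CRP-site
    generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
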