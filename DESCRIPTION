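Package: barriersearch
Title: Target-Barrier Search over Combinatorial Reaction Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding a chemical reaction whose activation barrier
    lies within a tolerance (by default 1 kcal/mol, chemical accuracy) of a
    desired target value, from a prespecified reaction space enumerated
    combinatorially from a core structure and interchangeable functional
    groups. Provides symmetry-aware enumeration and canonicalization of
    R-group schemes, one-hot reaction encodings optionally augmented with a
    cheap low-level barrier feature, ridge-regression imputation of missing
    low-level barriers, an active-learning ridge-guided search together with
    five baseline algorithms (random, local, guided local, Bayesian
    optimization, genetic), a benchmark harness with target grids and
    region-averaged sample counts, and a synthetic barrier-landscape
    generator so the full pipeline can be exercised without quantum
    chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    randomForest,
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
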