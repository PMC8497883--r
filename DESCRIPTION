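Package: tskfs
Title: Interpretable TSK Fuzzy Classifiers with Subspace-Clustered Antecedents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains first-order Takagi-Sugeno-Kang (TSK) fuzzy classifiers for
    binary recognition tasks on tabular features such as atlas region-of-interest
    (ROI) intensities from brain imaging. Rule antecedents are learned by a
    feature-weighted fuzzy subspace clustering algorithm in which every cluster
    carries its own feature-weight vector on the probability simplex, so each
    fuzzy rule keeps only a small activated feature subset; consequents are
    fitted as a ridge-regularized linear model over normalized rule firing
    strengths. Includes model-complexity accounting, linguistic rule-base
    rendering, synthetic-data generators with known ground truth, a Fisher-score
    feature selector, an atlas ROI mean-intensity extractor for NIfTI volumes,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
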