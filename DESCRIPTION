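Package: noteredund
Title: Copy-Paste Redundancy Analysis and Mitigation for Clinical Note Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies copy-paste redundancy in longitudinal clinical note
    corpora and mitigates its distorting effect on corpus statistics.
    Measures pairwise redundancy by token-level Smith-Waterman local
    alignment with repeated segment extraction, detects redundancy-induced
    deviations from Zipf's law in term frequency spectra, audits PMI/TMI
    bigram collocations for low patient support, and evaluates LDA topic
    models (collapsed Gibbs sampling with left-to-right held-out
    likelihood) on corpora of varying redundancy. Includes a line-based
    selective-fingerprinting greedy algorithm that builds sub-corpora with
    a bounded level of redundancy, a last-note-per-patient metadata
    baseline, and seeded synthetic corpus generators (patient-grouped
    notes with controllable copy-paste fraction, uniform xK duplication,
    non-uniform sK sampling) so every claim is testable without access to
    protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
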