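Package: coopnet
Title: Co-Occurring Opinion Networks from Free-Association Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed co-occurrence networks from multiple-response
    free-association survey data. Association pairs are weighted by a signed
    log-likelihood-ratio (LLR) collocation statistic, opinion modules are
    detected by signed-modularity Louvain consensus clustering, and the
    resulting modules are validated three ways: by the relation between
    co-occurrence strength and affective (emotion-label) similarity, by
    cross-sample reproducibility against edge-, weight- and
    strength-preserving null models (QAP permutation correlations and
    normalized mutual information), and by weighted attitude-score
    comparisons between modules. Includes a synthetic respondent-population
    generator with planted opinion groups for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    igraph,
    stringi,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
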