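Package: kgrepur
Title: Explainable Rule-Based Knowledge-Graph Completion for Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for explainable drug repurposing on heterogeneous
    biomedical knowledge graphs. Mines metapath rules bottom-up from
    observed "compound treats disease" triples by random-walk sampling and
    generalisation, scores rule confidence, and aggregates per-rule
    evidence into candidate scores (maximum, noisy-OR, non-redundant
    noisy-OR). A trainable autoregressive rule generator and a
    log-linear reasoning predictor are optimised jointly by
    expectation-maximisation for the single target relation, yielding
    ranked candidate diseases together with scored rules. Every
    prediction is explainable: rules and grounded paths are rendered in
    natural language and as Cypher queries. Includes a filtered-rank
    evaluation protocol (MRR, Hits@k, exact binomial confidence
    intervals), a seeded generator of synthetic typed knowledge graphs
    with planted metapaths for end-to-end testing, and readers/writers
    for tab-separated triple files including the Hetionet edge dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
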