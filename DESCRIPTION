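Package: relexr
Title: Joint Relational Triple Extraction with Adversarial Embedding Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts (subject, relation, object) triples from sentences with a
    three-stage joint model: a multi-label relation classifier built on
    multi-level pooled sentence representations, a global correspondence
    matrix scoring subject/object start-position pairs, and
    relation-conditioned BIO sequence taggers driven by self-attention.
    Training adds fast-gradient-method (FGM) perturbations at the word
    embedding layer in a two-pass gradient schedule. Includes a
    template-based synthetic corpus generator emulating the overlap-pattern
    statistics of plant-attribute text (Normal/SEO/EPO/SOO patterns),
    exact-match micro precision/recall/F1 evaluation stratified by pattern
    and triple count, JSON-lines corpus I/O, and knowledge-graph export
    (CSV, GraphML). The neural components run on a small built-in
    reverse-mode automatic differentiation engine over base R matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
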