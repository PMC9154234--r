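Package: acrosim
Title: Simulation and Annotation of Global Acronym Usage in Scientific Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds labelled training data for biomedical acronym sense
    disambiguation without manual annotation. Acronym definitions of the
    form "long form (SF)" are recognized in scientific abstracts by
    parenthetical pattern matching plus heuristic character alignment of
    the acronym against its full form. Each document is then rewritten to
    use, per acronym, either the acronym or its full form consistently;
    whenever a full form is removed it is retained as the sense
    annotation. Long-form variants are unified into a sense inventory
    (optionally via an offline concept-identifier map), ambiguous
    acronyms are turned into sentence-level binary verification samples
    with per-acronym train/validation/test reservation, and a
    most-frequent-sense baseline is provided for evaluation. A
    synthetic-corpus generator with exact ground truth makes every
    pipeline stage testable offline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
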