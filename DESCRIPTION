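Package: regenpath
Title: Reverse Pathway Analysis of Postnatal Myocardial Regeneration Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies genes as early or late postnatally upregulated after
    neonatal myocardial infarction from bulk RNA-seq count matrices, using
    median-of-ratios normalization, fold-change and error-bar separation
    criteria, an exact small-sample concordance p-value, and decides which
    candidate signaling pathways are comprehensively upregulated by checking
    initiator-to-effector chains over packaged pathway graphs. Includes a
    negative-binomial count simulator with planted ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
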