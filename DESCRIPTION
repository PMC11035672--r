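Package: crowdseg
Title: Quality-Controlled Crowdsourced Segmentation Annotation
Version: 0.1.0
Authors@R: person("crowdseg", "maintainers", email = "crowdseg@example.org",
    role = c("aut", "cre"))
Description: A quality-control engine for crowdsourced pixel-level
    segmentation of soft tissue. Implements annotator qualification by
    training score and continuous running-score monitoring against expert
    gold annotations, pixel-wise majority-vote consensus fusion, a
    difficulty index from inter-annotator agreement, review-threshold
    routing for expert quality assurance, standard segmentation agreement
    metrics (IoU, F1, accuracy, sensitivity, specificity), and campaign
    cost accounting. Ships a synthetic scene and annotator simulator so
    the whole pipeline is testable with known ground truth and no
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
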