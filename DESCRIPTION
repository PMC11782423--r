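Package: cadeval
Title: Standalone Performance Evaluation of Lesion-Detection CAD Systems
Version: 0.1.0
Authors@R: person("cadeval", "maintainers", email = "cadeval@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate the standalone performance of computer-aided
    detection (CAD) systems for pulmonary nodules on CT: 3D
    intersection-over-union matching of CAD findings to ground-truth
    annotations, scan- and nodule-level scoring, Wilson / Clopper-Pearson /
    Rao-Scott confidence intervals, ROC / precision-recall / FROC analysis
    with DeLong intervals, characterization concordance and Bland-Altman
    size agreement, reader-adjudication reference-standard construction,
    and a synthetic cohort plus simulated-detector generator so the whole
    pipeline can be exercised and verified without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
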