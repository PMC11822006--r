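Package: subitools
Title: Analysis of Deep-Subiculum Neuron Imaging, Morphometrics and Biophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying functionally specialized neuron classes in the
    deep subiculum. Implements peri-event statistics for one-photon
    miniscope calcium imaging during object-recognition behavior (z-scored
    responses, responder classification, peak-percentile statistics),
    spatial/speed/mobility tuning with circular-shift null distributions,
    FISH-based cell-body phenotyping (percent area covered, phenotype index,
    alveus-registered shape features), single-neuron axon-projection profile
    clustering, and a passive/active multicompartment cable model on SWC
    morphologies with dendritic-ablation experiments. Seeded synthetic-data
    generators with known ground truth make every stage testable without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    EBImage,
    uwot,
    class,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
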