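Package: flysteer
Title: Closed-Loop Guidance Simulator for Walking Flies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates closed-loop steering of freely walking fruit flies by
    visual (rotating pinwheel) and olfactory (lateralized red/blue
    optogenetic) guidance cues. Provides a stochastic walking-fly agent with
    tunable per-stimulation compliance, stepwise bang-bang heading
    controllers with goal sequencing, task environments (point-to-point
    shuttling, stroke-font letter writing, a looping maze with dead ends,
    pushable-ball relocation, load carrying, multi-fly writing and formation
    control), a synthetic imaging and blob-tracking path, and the standard
    trajectory readouts: fidelity scores over stimulation windows, success
    ratios under a 60-second rule, occupancy heatmaps, grouped fidelity time
    courses, ball-relocation statistics and fly-proximity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
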