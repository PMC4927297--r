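Package: calyxcycle
Title: Joint Kinetic Analysis of Presynaptic Membrane and Vesicle-Protein
    Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses paired membrane-capacitance and
    pH-sensitive reporter (cypHer/pHluorin-class) recordings from large
    presynaptic terminals such as the calyx of Held. Provides a fully seeded
    generator of capacitance jump-and-recovery traces with matched
    fluorescence quench traces (Henderson-Hasselbalch pH mapping, delayed
    exponential organelle re-acidification, photobleaching, neighbour-ROI
    references, extracellular acid puffs), bi-exponential-with-plateau fits
    of endocytotic capacitance recovery, bleach correction and quench-trace
    normalisation, a convolution forward model of reporter de-quenching with
    least-squares recovery of the re-acidification onset delay and time
    constant, acid-puff surface-pool metrics, and mean/SEM/t-test summaries.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
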