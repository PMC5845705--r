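Package: calmea
Title: Joint Calcium-Imaging and Microelectrode-Array Analysis of
    Developing Neuronal Network Synchrony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired single-cell calcium imaging and
    multi-electrode array (MEA) recordings of developing neuronal networks.
    Segments somata from fluorescence movies with a marker-controlled
    watershed, links them into cell tracks by gated Hungarian assignment,
    extracts normalized fluorescence traces, detects extracellular spikes
    with a robust median-based threshold, builds network activity traces,
    detects activity peaks by topographic prominence, quantifies
    pharmacological responses (GABA, GABA-A blockade, gap-junction
    blockade, high potassium), and classifies network activity as
    synchronous, loosely synchronous or asynchronous. A synthetic-data
    generator produces paired movies and voltage recordings with known
    ground truth so every stage is verifiable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    stats,
    utils,
    jsonlite,
    tiff,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
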