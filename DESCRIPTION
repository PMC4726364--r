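Package: nucpatterns
Title: Nucleosome Positioning Patterns Around Regulatory Elements from
    MNase-Seq Fragment Midpoints
Version: 0.1.0
Authors@R:
    person("Kei", "Tanaka", email = "ktanaka@example.org",
           role = c("aut", "cre"))
Description: Aggregates MNase-seq fragment midpoints into smoothed,
    RPM-normalized average nucleosome density profiles around classes of
    genomic anchors (cis-regulatory elements, transcription-factor
    binding sites, transcription start sites), extracts a small
    principal-component basis of recurring positioning patterns,
    decomposes individual profiles into signed pattern weights and
    composition ratios, characterizes pattern shapes by Morlet-wavelet
    scalograms and nucleosome co-positioning (cosine-similarity)
    matrices, and relates patterns to neighbouring gene expression via
    principal-component and ridge regression.  A synthetic-data module
    generates fragment sets, anchors, and expression tables with planted
    pattern structure so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
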