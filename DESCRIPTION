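Package: fluxscreen
Title: Simulation and Analysis of FACS-Based Pooled shRNA Autophagy
    Reporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for tandem mCherry-EGFP-LC3B reporter screens of
    autophagic flux. Provides a generative simulator of a pooled shRNA
    FACS sort-and-sequence screen (library manifests, per-cell reporter
    fluorescence, GFP-high/GFP-low gating, multinomial sequencing
    counts, error-free FASTQ), exact barcode/guide counting into an
    shRNA-by-sample count matrix, reads-per-million normalization with
    replicate geometric-mean fold-enrichment scoring and gene-level hit
    calling, flow-cytometry autophagic-flux quantification
    (percent-of-control summaries, percentile gates, gate percentages),
    and object-based 3D colocalization (difference-of-Gaussians spot
    segmentation, overlap-fraction double-positive classification,
    vesicle containment percentages, line profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
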