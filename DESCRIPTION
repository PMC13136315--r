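Package: photobarcode
Title: Light-Directed Combinatorial DNA Barcoding: Design, Simulation and Demultiplexing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial-omics experiments that build DNA barcodes in
    situ by light-directed ligation of short oligonucleotide "letters".
    Constructs combinatorial codebooks (m letters over n rounds give m^n
    barcodes in m x n ligation steps), derives the illumination schedule and
    optional binary light masks for each ligation step, models on- and
    off-target letter addition with a closed-form barcode-length
    distribution (a convolution of two binomials) and estimates the
    per-round on-target probability d and per-reaction off-target
    probability c from observed length fractions, fits capillary
    electropherogram traces as constrained sums of Gaussians to recover
    barcode-length proportions, demultiplexes paired-end sequencing reads by
    decoding the barcode letters in Read 1, and generates fully synthetic
    experiments (molecules, traces, paired FASTQ with ground truth) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
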