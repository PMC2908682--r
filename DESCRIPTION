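Package: mimdesign
Title: Design and Validation of Artificial MicroRNA Target Mimics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A design and validation toolkit for plant artificial miRNA target
    mimics. Converts mature miRNA sequences into IPS1-style non-cleavable decoy
    sites carrying a three-nucleotide bulge opposite the RISC cleavage position,
    partitions miRNA families into subfamilies that each need their own mimic,
    predicts cross-family capture, and assembles the final construct sequence
    together with overlap-extension mutagenesis primers. Includes a
    deterministic generator of synthetic miRNA catalogues and backbones with
    controlled family structure so the whole pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
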