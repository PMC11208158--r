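Package: bridgerec
Title: Bridge RNA Design and Recombination Simulation for IS110-Family
    Recombinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for the IS110/IS621 bridge-RNA recombination system: an
    annotated model of the 177-nt bridge RNA scaffold with its target- and
    donor-binding loops, a design engine that reprograms the guide segments
    (LTG, RTG, LDG, RDG and the handshake guides) against arbitrary 14-bp
    target and donor recognition windows, a sequence-level state-machine
    simulator of the four-step recombination reaction (top-strand cleavage,
    handshake-gated strand exchange, Holliday-junction formation and
    bottom-strand resolution) with covalent 5'-phosphoserine bookkeeping and
    heteroduplex annotation, and a signed, normalized nucleotide covariation
    score between DNA-site and bridge-RNA alignment columns ranging from -1
    (top-strand pairing) to +1 (bottom-strand pairing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
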