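Package: modmotif
Title: De Novo Methylated-Motif Discovery from Nanopore Modification Fraction Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of per-base DNA modification fractions from
    nanopore modification callers: control-compared differential tracks,
    extraction of the most strongly modified fixed-width regions, de novo
    motif discovery with a two-strand ZOOPS (zero-or-one-occurrence-per-
    sequence) expectation-maximisation algorithm, motif-anchored mean-fraction
    profiling with one-position extension ladders, methylation-aware in-silico
    restriction digestion (DpnI-style), per-read Phred quality summaries, and
    monoisotopic-mass annotation of modified nucleosides from observed m/z
    peaks. Includes a seeded synthetic-data generator that plants a
    methylation motif in a random genome so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
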