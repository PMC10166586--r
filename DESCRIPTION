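Package: motifcomp
Title: Decomposition, Encoding, Alignment and Visualization of Tandem Repeat Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring the motif composition of tandem repeat (TR)
    alleles. Each allele is optimally parsed into a sequence of motif-aligned
    segments by dynamic programming (emitting novel motifs where segments match
    no supplied motif), distinct motifs are encoded as single-character symbols,
    the encoded alleles are multiply aligned with a motif-similarity scoring
    matrix, rows are rearranged (hierarchical clustering, motif count, length,
    lexicographic or manual order), and the result is rendered as a color-coded
    motif-composition figure with a motif/frequency table. Includes a synthetic
    tandem-repeat allele simulator and brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
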