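Package: grnevolve
Title: In Silico Evolution of Gene Regulatory Networks for Terminal Cell
    Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves gene regulatory networks that drive multicellular
    terminal differentiation. Gene expression is computed with a
    thermodynamic (statistical-mechanics) model of transcription over
    mutable promoter strings: position weight matrices are scanned against
    promoters on both strands, thresholded binding sites contribute
    Boltzmann weights to the promoter partition function, and occupancy of
    the basal transcriptional machinery is integrated over developmental
    time, optionally coupled to a continuous chromatin-accessibility layer.
    Populations of genomes evolve under tournament selection with
    recombination and a scheduled mutation rate toward predefined optimal
    expression patterns. Evolved networks are analysed by in-silico
    mutagenesis (binding-site and transcription-factor knockouts),
    binding-site persistence tracking, and typed network-motif enumeration
    with Z-scores against degree-preserving randomized networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
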