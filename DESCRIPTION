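Package: segscan
Title: Detection of Segmental Exchange in Multigene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising segmental exchange (gene
    conversion / micro-recombination) among closely related paralogs of a
    multigene family. Provides p-distance neighbour-joining trees with
    bootstrap support, Nei-Gojobori synonymous/non-synonymous counting with a
    bootstrap Z-test of selection, the pairwise homoplasy index (PHI)
    recombination test, a scan for clustered nucleotide differences with a
    Monte Carlo significance assessment, cassette excision with
    topology-shift analysis and donor attribution, tandem repeat-unit
    decomposition, and a gene-family simulator (point mutation under JC69,
    planted conversion tracts, neutral coding evolution, repeat copy-number
    variation) that supplies ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
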