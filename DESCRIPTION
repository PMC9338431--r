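Package: numtforge
Title: Discovery and Molecular Evolution of Nuclear Mitochondrial Insertions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting nuclear copies of mitochondrial DNA (numts)
    in genome assemblies and for characterising their evolutionary history.
    Provides a homology scan of a mitogenome against a nuclear assembly with
    length filtering and fragment clustering, genetic-code-aware reading-frame
    classification of numt-resident genes, Nei-Gojobori (1986) pairwise dN/dS
    estimation with Fisher exact significance, Tajima-Nei distances and
    neighbour-joining trees, and a maximum-likelihood codon substitution model
    suite (one-ratio, two-ratio, site and clade models in the Goldman-Yang
    family) with likelihood-ratio tests. A synthetic-data module simulates
    mitogenomes, nuclear genomes with planted insertions of controlled age and
    donor lineage, and codon alignments evolved under the selection models,
    providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    rtracklayer,
    GenomicRanges,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
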