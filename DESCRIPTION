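Package: mirphas
Title: Small RNA Discovery of miRNAs, Phased siRNA Loci and Their Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing toolkit for paired
    (treatment vs control) libraries from plant tissue: FASTQ quality
    filtering, 3' adapter trimming and read accounting, collapsing to
    unique tags with category annotation (Rfam contaminants, repeats,
    exons, known miRNAs), hairpin-based novel miRNA prediction under the
    eleven classical precursor/duplex criteria, reads-per-million
    differential expression between two unreplicated libraries, detection
    of 21-nt phased siRNA (PHAS) loci with a hypergeometric window
    p-value and phasing score plus 22-nt trigger miRNA assignment, and
    rule-based plant miRNA target prediction with complementarity
    expectation scoring. A synthetic data generator plants hairpins,
    phased loci and contaminants into toy genomes so that every stage can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
SystemRequirements: ViennaRNA (RNAfold on the PATH) for thermodynamic
    folding; a pure-R base-pair maximisation folder is bundled as a
    fallback engine.
Config/testthat/edition: 3
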