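Package: modannot
Title: Annotation and Metagene Profiling of mRNA Modification Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps RNA modification sites or peaks (BED) onto transcript models
    (GTF + genome FASTA) and produces a full annotation suite: priority-resolved
    feature and biotype assignment, metagene and boundary-coverage profiles with
    confidence bands, gene-characteristic comparisons, k-mer motif enrichment
    with motif-guided exact-site refinement, hypergeometric gene-set enrichment,
    and group or gene-set comparative analyses. Includes a deterministic
    synthetic transcriptome and site generator for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
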