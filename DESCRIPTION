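Package: phasir
Title: Phased Small RNA Locus Detection and Methylation Metaprofiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the small-RNA and DNA-methylation landscape of
    plant reproductive tissue from aligned small-RNA reads and per-cytosine
    bisulfite calls. Calls small-RNA clusters by reads-per-million filtering and
    gap-based merging, classifies phased siRNA (phasiRNA) loci with a
    register-maximised hypergeometric phase statistic, overlaps loci with genes,
    transposable-element superfamilies and miRNA annotations, computes
    missing-data-aware anchored metaprofiles of cytosine methylation (CG, CHG,
    CHH), feature presence and GC content around locus sets, and performs
    library-level bookkeeping: size distributions, alignment-rate arithmetic,
    expression ratios, fold-change flags, sample correlations and MA values.
    Includes a fully deterministic synthetic-data generator (genome, annotation,
    phased read stacks, methylome) so the entire pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    methods,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
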