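Package: tracseq
Title: TRAC-Seq m7G tRNA Modification Calling and Codon-Dependent
    Translation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing N7-methylguanosine (m7G) tRNA
    modification by chemical reduction-and-cleavage sequencing
    (TRAC-seq) and its downstream consequences for mRNA translation.
    Builds mature tRNA references (intron excision, CCA addition),
    computes per-site read-start pileups, cleavage ratios and cleavage
    scores, calls m7G sites in the variable-loop window, quantifies
    tRNA expression (exclusive-mapping read counting, RPKM, fold
    changes), computes polysome-based translation efficiency and its
    dependence on the frequency of codons decoded by m7G-modified
    tRNAs, and generates fully synthetic TRAC-seq and polysome
    profiling experiments with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    BiocGenerics,
    GenomicAlignments,
    Rsamtools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
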