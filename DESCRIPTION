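Package: minidbg
Title: Minimizer-Space de Bruijn Graph Assembly of Accurate Long-Read Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A metagenome assembler for accurate long reads (PacBio HiFi-like,
    around 99.9 percent per-base accuracy) that works in minimizer space.
    Reads are homopolymer-compressed and converted to ordered lists of
    universal minimizers (mReads); a de Bruijn graph over windows of k'
    consecutive minimizers (k'-min-mers) is assembled iteratively for
    increasing k', with abundance-aware error filtering, tip clipping,
    superbubble popping and a local progressive abundance filter that
    recovers genomes across a wide range of coverage depths. Final
    minimizer-space contigs are converted back to nucleotide sequence by
    minimizer-space read mapping, polished with a window consensus, and
    purged of strain duplications. Includes a synthetic HiFi-like community
    simulator with ground truth and a reference-based evaluation of assembly
    completeness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
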