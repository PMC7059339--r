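Package: saltlnc
Title: Discovery and Functional Prediction of Salt-Responsive Long
    Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide discovery and functional
    prediction of long noncoding RNAs (lncRNAs) from a salt-stress time
    course. Assembled transcript models are reduced to lncRNA candidates
    by a basic filtering cascade (recurrence, same-strand gene overlap,
    length, read coverage, open reading frame length), scored for coding
    potential (Fickett TESTCODE, in-frame hexamer bias, a trainable
    logistic combiner, and a conservative consensus call), and classified
    as antisense or intergenic. Differential expression over the time
    course is called with a negative-binomial exact test and
    Benjamini-Hochberg FDR control. Trans-acting function is predicted by
    topological-overlap co-expression modules, temporal archetype
    assignment and Fisher enrichment of functional categories; cis-acting
    candidates by asymmetric genomic windows plus expression correlation;
    and miRNA-lncRNA targeting by ungapped complementarity scanning with
    mismatch and G:U wobble accounting. A synthetic-data generator with
    planted ground truth emulates every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
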