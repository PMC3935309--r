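Package: novotx
Title: Discovery of Unannotated Transcription and Splice-Junction
    Classification from RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Window-based discovery of unannotated intronic and intergenic
    transcription from uniquely mapped RNA-Seq read positions, using a
    Poisson enrichment test against compartment-specific background
    intensities estimated by maximum likelihood, Benjamini-Hochberg false
    discovery rate correction, and merging of significant windows into
    high coverage peaks (HCPs).  Also provides a hierarchical
    seven-category classifier of splice junctions (annotated, exon
    skipping, only one side, intra-exonic, different transcripts,
    trans-splicing, intronic/intergenic) against a gene annotation, and a
    synthetic-data generator producing annotation, reads and junctions
    with known ground truth.  Functions take data frames and return
    tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
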