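Package: polymethyl
Title: Sub-Genome Resolved Bisulfite Methylation Analysis for Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Targeted bisulfite sequencing analysis for allopolyploid genomes,
    built around homoeologous-SNP-driven assignment of reads to sub-genomes
    (A, B and D in hexaploid bread wheat). Provides a ground-truth synthetic
    data generator (homoeologous references, methylation truth, bisulfite
    reads with incomplete conversion, an unmethylated control contig and
    allelic expression), readers and writers for SAM alignments carrying
    methylation call strings, SNP catalogues, region annotations and
    expression tables, cytosine context classification (CpG/CHG/CHH),
    bisulfite conversion rate estimation, per-site per-sub-genome methylation
    tallies with coverage gates, polyploid-specific methylation state calling,
    uni-/bi-/tri-genome pattern classification with Fisher exact tests and
    Benjamini-Hochberg q-values, per-region differential methylation (DMR)
    calling, and integration of methylation patterns with normalized allelic
    expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    e1071,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
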