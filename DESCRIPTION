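Package: methdiff
Title: Differential DNA Methylation Analysis for WGBS Call Tables
Version: 0.1.0
Authors@R: person("Maintainer", "methdiff", email = "methdiff@example.org",
    role = c("aut", "cre"))
Description: Tools for differential DNA-methylation analysis of whole-genome
    bisulfite sequencing (WGBS) CpG call tables across treatment conditions:
    joint coverage filtering, per-CpG Fisher-exact differential methylation
    calling (DMPs), sliding-window extraction of differentially methylated
    regions (DMRs) with density and window-count filters, hierarchical
    clustering of DMPs into methylation modules, genomic-feature fold
    enrichment, methylation-expression integration through promoter and
    chromatin-interaction anchors, nucleosome-occupancy profile aggregation,
    and a synthetic WGBS-like data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
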