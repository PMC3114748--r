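Package: ffg
Title: Bulk-Segregant Mapping and EMS Mutation Identification from Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("ffg", "maintainers", email = "ffg@example.org", role = c("aut", "cre"))
Description: Tools for two-step forward-genetics mutation mapping from pooled
    sequencing data. Simulates an EMS-mutagenized F2 bulk-segregant cross and
    its pooled sequencing, discovers and genotypes pool SNPs under strict
    coverage/strand/start-site filters (merging pools into a "virtual F1"),
    localizes the causal locus from binned mapping-allele frequencies,
    calls high-frequency candidate mutations in an enriched interval with
    coding-effect annotation, and designs tiling 60-mer capture probes for the
    linked region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    optparse,
    rlang,
    graphics,
    grDevices,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
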