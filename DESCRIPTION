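Package: dmrcall
Title: Binned Score-Test Calling of Differentially Methylated Regions in
    Sparse CG-Island Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing analysis of genomes
    whose methylation is concentrated in CG-methylated transposable-element
    islands, as in diatoms. Reads Bismark-style per-cytosine reports, assigns
    CG/CHG/CHH contexts from a reference genome, applies a multi-sample
    coverage filter, and calls 100-bp differentially methylated regions
    between a reference and a mutant methylome with a pooled two-proportion
    score test. Derives cross-replicate consensus hypomethylated regions,
    quantifies their overlap with gene, transposable-element and histone-mark
    annotations (direct and with regulatory windows), and integrates
    differential-expression tables to link methylation loss to
    transposable-element derepression. Includes a seeded synthetic-methylome
    generator with planted ground truth for parameter-recovery testing, and a
    pipeline orchestrator with a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    methods,
    IRanges,
    S4Vectors,
    data.table,
    digest,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
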