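Package: ggaareg
Title: GGAA-Microsatellite Enhancer Analysis for ETS Fusion Target Genes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline linking GGAA microsatellites bound by an ETS fusion
    oncoprotein (such as EWSR1-FLI1 in Ewing sarcoma) to regulated genes.
    Detects GGAA-family tandem microsatellites in DNA with an interruption
    model (GGAG units intercalated among GGAA units), assigns ChIP-seq peaks
    to genes by gene-body containment and by strand-aware nearest distance to
    the transcription start site, classifies genes as up-, down- or unregulated
    from differential-expression tables against a transcription-factor catalog,
    computes directional overlap statistics between regulated gene sets with an
    exact one-sided Fisher test and Benjamini-Hochberg annotation enrichment,
    correlates microsatellite allele length with expression, and generates
    fully synthetic inputs with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    IRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
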