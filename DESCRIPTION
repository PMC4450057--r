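Package: cissage
Title: Discovery and Characterization of Cis-Spliced Fusion RNAs Between
    Adjacent Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying cis-SAGe events (cis-splicing between
    adjacent genes, also called read-through or conjoined-gene fusions)
    from chimeric-RNA call tables. Classifies fusion calls against a gene
    annotation into interchromosomal, same-strand zero-gap, and other
    intrachromosomal categories; applies a six-criteria filtering cascade
    (Sanger confirmation, immediate neighborhood, absence of interstitial
    deletion, intergenic CTCF binding, induction under CTCF knockdown,
    intergenic transcript evidence); computes characterization statistics
    (genome-background Kolmogorov-Smirnov comparisons, exon-junction
    position histograms, an exact and simulated exon-2 usage test,
    coding-impact classification); and predicts novel read-through
    candidates genome-wide from four rules. Includes a synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
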