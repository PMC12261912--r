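Package: capdesign
Title: Targeted-Capture SNP Panel Design and Evaluation for Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs hybridization-capture SNP genotyping panels from
    multi-sample population variant calls using a three-phase selection
    procedure (structural filtering against repeat/centromere masks,
    adjacent-pair linkage-disequilibrium pruning, and adjacency refinement
    toward uniform genome-wide spacing with forced inclusion of loci inside
    GWAS/QTL target intervals), and evaluates designed panels and capture
    sequencing runs: per-site quality statistics, spacing and gene-annotation
    reports, probe detection rate and depth QC, chip-versus-WGS variant
    concordance, genotype PCA with out-of-sample projection, a single-marker
    association scan with principal-component covariates, and sliding-window
    nucleotide diversity, Hudson Fst and reduction-of-diversity selection
    scans with top-quantile region calling. Includes a seeded synthetic-data
    generator (island-model structured genotypes, selective sweeps, causal
    traits, capture-depth profiles) used as the test substrate.
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
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
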