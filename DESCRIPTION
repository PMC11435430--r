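Package: corepanel
Title: Core SNP Panel Design and Variety Identification for Clonal Crop Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a SNP-marker workflow for cultivated
    pear germplasm: genotype import (VCF and wide Fluidigm-style tables),
    locus-level quality filtering (minor allele frequency, missing rate, read
    depth), marker informativeness statistics (PIC, unbiased expected
    heterozygosity, rarefied allelic richness), population differentiation
    (Weir-Cockerham Fst with permutation tests, Nei's unbiased genetic
    distance), PCA and Euclidean/UPGMA clustering, chromosome-balanced core
    marker panel selection with nested subsets, and genotype-profile-based
    variety identification. Includes a Balding-Nichols multi-population
    genotype simulator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
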