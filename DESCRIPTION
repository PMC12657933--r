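Package: melscan
Title: Microbiome-Trait GWAS and Multiple-Effect-Locus Detection for Crop
    Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links genetic variation in structured crop diversity panels to
    in-vitro gut microbiome fermentation phenotypes. Provides trait
    processing for rarefied amplicon count tables (filtering, log2 and
    centered log-ratio transforms, alpha diversity), community-level
    statistics (Bray-Curtis, PERMANOVA, Kruskal-Wallis with
    Benjamini-Hochberg, Dunn's post hoc, principal coordinates),
    construction of polymicrobial score variables from MANOVA
    sums-of-squares-and-cross-products matrices (hypothesis and genetic
    covariance/correlation PCA, canonical discriminant analysis), kinship
    and BLUP mixed models with broad-sense heritability filtering, a
    genome-wide association scan with pseudo-QTN conditioning, and
    multiple-effect-locus (MEL) calling with linkage-disequilibrium-defined
    boundaries. A synthetic-data module simulates genotype panels with
    landrace/market-class structure, partially replicated fermentation
    designs, and count/metabolite responses with planted pleiotropic loci
    for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
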