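Package: fwparallel
Title: Genetic Parallelism and Diversity of Marine-Freshwater Ecotype Pairs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies genetic parallelism of repeated marine-to-freshwater
    adaptation from SNP data. Implements per-cluster principal component
    analysis of high-linkage-disequilibrium loci (from genotype likelihoods
    or by projection onto a reference-trained space), quadratic discriminant
    classification of individuals into marine or freshwater haplotype classes
    with leave-one-out model selection, the per-individual Probability of
    Freshwater Genotype and the population-level Parallelism Index. Also
    provides nucleotide diversity and heterozygosity from folded site
    frequency spectra, a genotype-likelihood runs-of-homozygosity caller,
    Weir-Cockerham F_ST, LD-cluster network construction and refinement,
    regional statistics (linear and gamma log-link models, one-way ANOVA with
    Tukey post-hoc tests, intraclass correlation, the gene-swamping
    inequality), and a Balding-Nichols synthetic-data generator with planted
    parallel clusters and autozygous tracts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
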