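Package: lowcovcall
Title: Simulation and Evaluation of Variant Calling for Low-Coverage
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulation and evaluation of genotype calling from
    low-coverage whole-genome sequencing of family cohorts. Simulates
    multi-generation pedigrees with admixed founders, LD-structured
    haplotypes, Poisson read pileups and exome-chip genotype sets with
    realistic artifacts (allele flips, duplicate samples, missingness);
    implements three caller classes (single-sample, multi-sample with an
    EM cohort-frequency prior, and LD-aware Li-Stephens haplotype-copying
    HMM refinement); and computes the comparison statistics used to
    benchmark them against chip genotypes: marker QC filters (duplicate
    discordance, Hardy-Weinberg exact test, flipped-marker concordance),
    per-sample concordance and false-positive rate, frequency-binned site
    discovery with a 1-(1-p)^f single-sample model, a genotype-likelihood
    sample-identity statistic for swap detection, pedigree and empirical
    kinship, and best linear unbiased (kinship-corrected) allele
    frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
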