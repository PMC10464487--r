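Package: clonepop
Title: Clonal Structure and Population Genetics of Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of diploid codominant
    microsatellite genotypes in partially clonal organisms such as brooding
    corals. Reads and writes genepop and two-column CSV genotype tables;
    detects multilocus genotypes (MLGs) and collapses them into multilocus
    lineages under a stepwise mutation model; computes clonal richness,
    Stoddart-Taylor genotypic diversity, evenness and diversity indices with a
    randomization test for sexual reproduction; estimates per-population locus
    statistics (heterozygosities, Weir-Cockerham FIS with bootstrap intervals,
    Hardy-Weinberg exact tests, a null-allele screen); computes pairwise
    Weir-Cockerham FST with permutation significance; fits a Bayesian admixture
    model by Gibbs sampling with Evanno delta-K model selection; provides DAPC,
    PCA, Nei distances and minimum spanning networks; and performs
    isolation-by-distance analysis with a Mantel test. Includes a forward
    simulator of multi-deme clonal microsatellite data with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
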