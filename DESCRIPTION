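Package: oakintro
Title: Microsatellite Population Structure, Introgression and Barrier
    Analysis for White Oaks
Version: 0.1.0
Authors@R:
    person("oakintro", "maintainers", email = "oakintro@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for nuclear and chloroplast microsatellite
    (SSR) analysis of hybridizing white oak populations: Bayesian admixture
    inference by Gibbs sampling with replicate-run alignment, mode detection
    and cluster-number selection metrics; classification of individuals into
    pure, admixed and highly admixed categories and a population-level
    introgression index; diversity and differentiation statistics (observed
    and expected heterozygosity, inbreeding coefficient, rarefied allelic
    richness, Nei's FST, Jost's D, principal coordinates analysis);
    Monmonier maximum-difference barrier detection on a Delaunay
    triangulation with locus-bootstrap support; chloroplast haplotype
    calling, minimum spanning networks and Pons-Petit haplotype diversity;
    and beta regression of the introgression index on environmental
    covariates with stepwise AIC selection and a variance-inflation loop.
    A synthetic-data generator with known truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
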