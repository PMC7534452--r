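Package: namqtl
Title: Simulation and Analysis of Nested Association Mapping RIL Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and evaluating nested association mapping
    (NAM) panels built from recombinant inbred line (RIL) populations that
    share a recurrent parent, modelled on a 14-population Arabidopsis
    thaliana panel design. Includes a founder-haplotype and F8 RIL
    simulator with a genotyping-by-sequencing (GBS) observation model,
    Kosambi linkage-map estimation, conservative fill-in imputation with a
    hidden-Markov genotype-probability filter, anchored projection of dense
    parental SNPs with a double-crossover error model, maximum-likelihood
    single-QTL genome scans with permutation thresholds and 1.5-LOD support
    intervals, kinship-corrected linear mixed-model association, linkage
    disequilibrium decay analysis, a two-locus allelic-incompatibility
    screen, and power-simulation pipelines over population subsets and
    marker densities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
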