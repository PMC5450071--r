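Package: germdiv
Title: Population-Genomic Characterization of Selfing Germplasm Collections
Version: 0.1.0
Authors@R:
    person("CNPAF", "Genomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for SNP-based characterization of crop germplasm
    collections with strong population structure and high selfing, such as
    common bean core collections split into Andean and Mesoamerican gene
    pools. Provides genotype import/export (VCF and wide DArT-style
    tables), marker quality control, per-group and hierarchical diversity
    statistics (He, Ho, F, FST, FIS, FIT, probability of identity and
    exclusion), non-overlapping window scans (Watterson's theta, pi,
    Tajima's D, Hudson FST), FST-outlier detection by a hierarchical-island
    simulation envelope and a Bayesian logistic-FST model, kinship- and
    structure-corrected linkage disequilibrium with Hill-Weir decay
    fitting, Gabriel confidence-interval haplotype blocks, LD pruning and
    SNP-panel selection, a lightweight EM admixture estimator,
    simple-matching/neighbor-joining dendrograms, spatial diversity grids,
    and a synthetic germplasm generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
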